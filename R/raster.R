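#' Construct a spike raster
#'
#' Event-list container for spiking output: one row per spike, plus
#' population/group/position metadata per neuron.
#'
#' @param neuron integer neuron ids (1-based).
#' @param time spike times in ms.
#' @param n_neurons total number of neurons.
#' @param pop optional character vector of population labels per neuron.
#' @param group optional integer group labels per neuron (feedforward-input
#'   groups).
#' @param positions optional `n_neurons` x 2 matrix of torus positions.
#' @param t_end end of the recorded interval (ms).
#' @param truncated whether the simulation was stopped early by the spike
#'   budget (unstable run).
#' @return a `spike_raster`.
#' @export
spike_raster <- function(neuron, time, n_neurons, pop = NULL, group = NULL,
                         positions = NULL, t_end = max(time, 0),
                         truncated = FALSE) {
  stopifnot(length(neuron) == length(time))
  structure(list(events = tibble(neuron = as.integer(neuron), time = as.numeric(time)),
                 n_neurons = as.integer(n_neurons), pop = pop, group = group,
                 positions = positions, t_end = t_end, truncated = truncated),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d spikes from %d neurons over %.0f ms%s\n",
              nrow(x$events), x$n_neurons, x$t_end,
              if (x$truncated) " (truncated: spike budget exceeded)" else ""))
  invisible(x)
}

#' Spike counts in non-overlapping windows
#'
#' @param raster a `spike_raster`.
#' @param window window length (ms).
#' @param ids neurons to count (columns of the result).
#' @param t_range analysis interval `c(t0, t1)`; defaults to the full
#'   recording.
#' @return matrix of counts, windows x neurons.
#' @export
spike_counts <- function(raster, window, ids = seq_len(raster$n_neurons),
                         t_range = c(0, raster$t_end)) {
  stopifnot(inherits(raster, "spike_raster"), window > 0)
  n_win <- floor((t_range[2] - t_range[1]) / window)
  if (n_win < 1) stopf("analysis interval shorter than one window")
  ev <- raster$events
  keep <- ev$time >= t_range[1] & ev$time < t_range[1] + n_win * window &
    ev$neuron %in% ids
  ev <- ev[keep, ]
  col <- match(ev$neuron, ids)
  win <- floor((ev$time - t_range[1]) / window) + 1L
  counts <- matrix(0L, n_win, length(ids),
                   dimnames = list(NULL, as.character(ids)))
  tab <- tabulate((col - 1L) * n_win + win, nbins = n_win * length(ids))
  counts[] <- tab
  counts
}
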