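#' Pairwise spike-count correlations
#'
#' Counts spikes in non-overlapping windows and computes the Pearson
#' correlation for every sampled pair. Pairs involving a neuron with
#' zero-variance counts are excluded (and reported), not zero-imputed.
#'
#' @param raster a [spike_raster()].
#' @param window count window (ms); 250 ms follows the balanced-network
#'   convention.
#' @param sample neuron ids to correlate; defaults to up to `n_sample`
#'   excitatory neurons (or all neurons if no population labels) sampled
#'   under `seed`.
#' @param n_sample sample size when `sample` is NULL.
#' @param seed sampling seed.
#' @param t_range analysis interval; pass the burn-in-trimmed window.
#' @param groups optional per-neuron group labels (indexed by neuron id)
#'   for a within/across breakdown.
#' @param breaks histogram breaks for the coefficient distribution.
#' @return a `correlation_summary` with `mean_corr`, `n_pairs`,
#'   `histogram`, optional `by_group`, and the count of excluded neurons.
#' @export
spike_count_correlations <- function(raster, window = 250, sample = NULL,
                                     n_sample = 1000, seed = 1,
                                     t_range = c(0, raster$t_end),
                                     groups = NULL,
                                     breaks = seq(-1, 1, by = 0.05)) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(sample)) {
    pool <- if (!is.null(raster$pop)) which(raster$pop == "e") else seq_len(raster$n_neurons)
    sample <- sort(with_seed(seed, sample(pool, min(n_sample, length(pool)))))
  }
  counts <- spike_counts(raster, window, ids = sample, t_range = t_range)
  sds <- apply(counts, 2, sd)
  ok <- sds > 0
  n_excluded <- sum(!ok)
  counts <- counts[, ok, drop = FALSE]
  sample <- sample[ok]
  if (ncol(counts) < 2) {
    return(structure(list(window = window, n_pairs = 0L, mean_corr = NA_real_,
                          histogram = NULL, by_group = NULL,
                          n_excluded = n_excluded, sample = sample),
                     class = "correlation_summary"))
  }
  cm <- cor(counts)
  ut <- upper.tri(cm)
  coefs <- cm[ut]
  by_group <- NULL
  if (!is.null(groups)) {
    g <- groups[sample]
    same <- outer(g, g, "==")[ut]
    by_group <- list(within = mean(coefs[same]), across = mean(coefs[!same]),
                     n_within = sum(same), n_across = sum(!same))
  }
  structure(list(window = window, n_pairs = length(coefs),
                 mean_corr = mean(coefs),
                 histogram = graphics::hist(coefs, breaks = breaks, plot = FALSE),
                 by_group = by_group, n_excluded = n_excluded,
                 sample = sample),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("spike-count correlations (%g ms windows): mean %.4f over %d pairs (%d neurons excluded)\n",
              x$window, x$mean_corr, x$n_pairs, x$n_excluded))
  if (!is.null(x$by_group)) {
    cat(sprintf("  within-group %.4f (%d pairs), across-group %.4f (%d pairs)\n",
                x$by_group$within, x$by_group$n_within,
                x$by_group$across, x$by_group$n_across))
  }
  invisible(x)
}

#' Spike-count correlation as a function of torus distance
#'
#' @inheritParams spike_count_correlations
#' @param positions `n_neurons` x 2 torus positions (defaults to the
#'   raster's).
#' @param bins distance bin breaks; the torus diameter is `sqrt(2)/2`, and
#'   the default stops at 0.7, dropping the statistically negligible
#'   corner sliver beyond it.
#' @return a tibble with `distance` (bin centers), `mean_corr`, `n_pairs`
#'   (empty bins reported with `NA` mean).
#' @export
correlation_vs_distance <- function(raster, positions = raster$positions,
                                    window = 250, bins = seq(0, 0.7, by = 0.05),
                                    sample = NULL, n_sample = 1000, seed = 1,
                                    t_range = c(0, raster$t_end)) {
  if (is.null(positions)) stopf("positions are required")
  if (is.null(sample)) {
    pool <- if (!is.null(raster$pop)) which(raster$pop == "e") else seq_len(raster$n_neurons)
    sample <- sort(with_seed(seed, sample(pool, min(n_sample, length(pool)))))
  }
  counts <- spike_counts(raster, window, ids = sample, t_range = t_range)
  ok <- apply(counts, 2, sd) > 0
  counts <- counts[, ok, drop = FALSE]
  sample <- sample[ok]
  cm <- cor(counts)
  ut <- upper.tri(cm)
  p <- positions[sample, , drop = FALSE]
  dx <- abs(outer(p[, 1], p[, 1], "-"))
  dy <- abs(outer(p[, 2], p[, 2], "-"))
  dist <- sqrt(pmin(dx, 1 - dx)^2 + pmin(dy, 1 - dy)^2)[ut]
  coefs <- cm[ut]
  bin <- cut(dist, bins, include.lowest = TRUE)
  tibble(distance = (utils::head(bins, -1) + utils::tail(bins, -1)) / 2,
         mean_corr = as.numeric(tapply(coefs, bin, mean)),
         n_pairs = as.integer(table(bin)))
}

#' Classify a raster as synchronous or asynchronous
#'
#' Bins the population rate, smooths it with a Gaussian kernel, and
#' compares the peak to the time-averaged rate: synchronous volleys give a
#' peak many times the mean, while asynchronous (balanced) firing keeps
#' the ratio near 1. An empty raster is asynchronous with index 0. The
#' verdict is a deterministic function of the raster and the parameters.
#'
#' The default threshold of 4 was calibrated on reference-scale
#' simulations: asynchronous balanced runs and Poisson surrogates
#' concentrate below 2, while full-population volley states sit above 6
#' (the smoothed mean rate in a volley state is inflated by inhibitory
#' neurons spiking several times per volley, which caps the peak-to-mean
#' index of even unambiguous synchrony near 7).
#'
#' @param raster a [spike_raster()].
#' @param bin population-rate bin (ms).
#' @param sigma Gaussian smoothing width (ms).
#' @param threshold synchrony threshold on the peak/mean index.
#' @param t_range analysis interval.
#' @return a `synchrony_verdict` with `synchronous`, `sync_index`,
#'   `threshold`.
#' @export
classify_synchrony <- function(raster, bin = 2, sigma = 5, threshold = 4,
                               t_range = c(0, raster$t_end)) {
  stopifnot(inherits(raster, "spike_raster"))
  t0 <- t_range[1]
  t1 <- min(t_range[2], raster$t_end)
  ev <- raster$events$time
  ev <- ev[ev >= t0 & ev < t1]
  n_bins <- max(1L, floor((t1 - t0) / bin))
  if (length(ev) == 0 || n_bins < 3) {
    return(structure(list(synchronous = FALSE, sync_index = 0,
                          threshold = threshold), class = "synchrony_verdict"))
  }
  counts <- tabulate(pmin(floor((ev - t0) / bin) + 1L, n_bins), nbins = n_bins)
  rate <- gaussian_smooth(counts, sigma, dt = bin)
  idx <- max(rate) / mean(rate)
  structure(list(synchronous = idx > threshold, sync_index = idx,
                 threshold = threshold), class = "synchrony_verdict")
}

#' @export
print.synchrony_verdict <- function(x, ...) {
  cat(sprintf("%s (sync index %.2f, threshold %g)\n",
              if (x$synchronous) "synchronous" else "asynchronous",
              x$sync_index, x$threshold))
  invisible(x)
}

#' Rheobase of an EIF population
#'
#' The minimal constant input (in mV/ms, current per capacitance) at which
#' the EIF's resting state disappears. The subthreshold balance
#' `(V - E_L)/tau_m - (Delta_T/tau_m) exp((V - V_T)/Delta_T)` is maximized
#' at `V = V_T`, giving `(V_T - E_L - Delta_T) / tau_m`.
#'
#' @param params a [network_params()].
#' @param pop `"e"` or `"i"`.
#' @return rheobase in mV/ms.
#' @export
#' @examples
#' rheobase(network_params(), "e") # 8/15
rheobase <- function(params, pop = "e") {
  stopifnot(inherits(params, "network_params"), pop %in% c("e", "i"))
  unname((params$v_t - params$e_l - params$delta_t[pop]) / params$tau_m[pop])
}

#' Normalized shared-current decomposition
#'
#' Averages the recorded input currents across neurons per component
#' (feedforward, recurrent excitatory, recurrent inhibitory), smooths with
#' a Gaussian kernel, subtracts the mean over the analysis window, and
#' divides by the neurons' rheobase. In a balanced network the recurrent
#' trace tracks and cancels the feedforward trace, leaving a small total.
#'
#' @param currents a `current_record` from [simulate_network()].
#' @param params the [network_params()] used for the run (for the
#'   rheobase).
#' @param kernel_sigma smoothing width (ms).
#' @param t_range analysis interval (ms); defaults to the full recording.
#' @return a `shared_fluctuation` with a tibble `traces` (`time`, `ffwd`,
#'   `rec_e`, `rec_i`, `rec_total`, `total`), each trace zero-mean over
#'   the window.
#' @export
shared_current_decomposition <- function(currents, params, kernel_sigma = 15,
                                         t_range = NULL) {
  stopifnot(inherits(currents, "current_record"))
  keep <- if (is.null(t_range)) {
    rep(TRUE, length(currents$time))
  } else {
    currents$time >= t_range[1] & currents$time < t_range[2]
  }
  pop <- if (all(currents$pop == "i")) "i" else "e"
  rheo <- rheobase(params, pop)
  norm_trace <- function(m) {
    tr <- gaussian_smooth(rowMeans(m[keep, , drop = FALSE]), kernel_sigma,
                          dt = currents$dt_sample)
    (tr - mean(tr)) / rheo
  }
  f <- norm_trace(currents$ffwd)
  re <- norm_trace(currents$rec_e)
  ri <- norm_trace(currents$rec_i)
  structure(list(traces = tibble(time = currents$time[keep], ffwd = f,
                                 rec_e = re, rec_i = ri,
                                 rec_total = re + ri, total = f + re + ri),
                 kernel_sigma = kernel_sigma,
                 n_sampled = ncol(currents$ffwd), rheobase = rheo),
            class = "shared_fluctuation")
}

#' Per-neuron and per-population firing rates
#'
#' @param raster a [spike_raster()].
#' @param t_range analysis interval (ms); pass the burn-in-trimmed window.
#' @return list with `per_neuron` (tibble `neuron`, `pop`, `rate_hz`) and
#'   `per_pop` (named mean rates).
#' @export
firing_rates <- function(raster, t_range = c(0, raster$t_end)) {
  stopifnot(inherits(raster, "spike_raster"))
  dur <- (t_range[2] - t_range[1]) / 1000
  if (dur <= 0) stopf("empty analysis interval")
  ev <- raster$events
  ev <- ev[ev$time >= t_range[1] & ev$time < t_range[2], ]
  n_spk <- tabulate(ev$neuron, nbins = raster$n_neurons)
  pop <- raster$pop %||% rep("all", raster$n_neurons)
  per_neuron <- tibble(neuron = seq_len(raster$n_neurons), pop = pop,
                       rate_hz = n_spk / dur)
  per_pop <- tapply(per_neuron$rate_hz, per_neuron$pop, mean)
  list(per_neuron = per_neuron, per_pop = per_pop)
}
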