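#' Ensheathment parameters for the effective astrocyte
#'
#' The microscale model shows that astrocyte protrusion reduces synaptic
#' strength and half-max width linearly, which the network model captures
#' by scaling both the synaptic weight and the synaptic time constant of an
#' ensheathed synapse by `(1 - s_en)`. Each recurrent synapse with an
#' excitatory (inhibitory) presynaptic neuron is independently ensheathed
#' with probability `p_e` (`p_i`). Feedforward synapses are never
#' ensheathed.
#'
#' @param s_en ensheathment strength in `[0, 1)`; connections are never
#'   fully removed, so `s_en` must stay below 1.
#' @param p_e probability that an excitatory recurrent synapse is
#'   ensheathed.
#' @param p_i probability that an inhibitory recurrent synapse is
#'   ensheathed.
#' @param mode which synaptic parameters ensheathment scales: `"both"`
#'   (weight and time constant, the default model), `"j_only"` (weight
#'   only), or `"tau_only"` (kinetics only) -- the dissociation variants.
#' @param seed integer seed for the per-synapse assignment; with a fixed
#'   seed the flagged synapse set is identical across modes, making the
#'   dissociation a controlled comparison.
#' @return an `ensheathment_params` object.
#' @export
#' @examples
#' ensheathment_params(s_en = 0.5, p_e = 0.7)
ensheathment_params <- function(s_en = 0, p_e = 0, p_i = 0,
                                mode = c("both", "j_only", "tau_only"),
                                seed = 1) {
  mode <- match.arg(mode)
  if (s_en < 0 || s_en >= 1) stopf("s_en must lie in [0, 1), got %g", s_en)
  if (p_e < 0 || p_e > 1 || p_i < 0 || p_i > 1) {
    stopf("ensheathment probabilities must lie in [0, 1]")
  }
  structure(list(s_en = s_en, p_e = p_e, p_i = p_i, mode = mode,
                 seed = as.integer(seed)),
            class = "ensheathment_params")
}

#' Which synaptic parameters a variant mode scales
#'
#' @param mode `"both"`, `"j_only"`, or `"tau_only"`.
#' @return list with logical `scale_j` and `scale_tau`.
#' @export
variant_mode <- function(mode) {
  if (length(mode) != 1 || !mode %in% c("both", "j_only", "tau_only")) {
    stopf("unknown ensheathment mode '%s'", paste(mode, collapse = ","))
  }
  list(scale_j = mode %in% c("both", "j_only"),
       scale_tau = mode %in% c("both", "tau_only"))
}

#' Assign per-synapse ensheathment indicators
#'
#' Flags each recurrent edge independently: edges with an excitatory
#' presynaptic neuron with probability `p_e`, inhibitory ones with `p_i`.
#' The assignment is a pure function of the connectivity and the
#' ensheathment seed (the mode plays no role), reproducible across calls.
#'
#' @param conn a `connectivity` from [build_nonspatial()] or
#'   [build_spatial()].
#' @param params an [ensheathment_params()].
#' @return logical vector with one entry per recurrent edge, in edge-table
#'   order.
#' @export
assign_ensheathment <- function(conn, params) {
  stopifnot(inherits(conn, "connectivity"),
            inherits(params, "ensheathment_params"))
  # edges are stored grouped by presynaptic neuron with the E population
  # first, so the E-presynaptic edges form a contiguous leading block
  n_edges <- length(conn$post)
  n_e_edges <- conn$pre_ptr[conn$n_e + 1L]
  flags <- logical(n_edges)
  chunk <- 10000000L
  with_seed(params$seed, {
    # chunked draws keep transient memory bounded at reference sizes
    # (the uniform stream is identical to a single runif call)
    if (n_e_edges > 0) {
      for (i0 in seq(1L, n_e_edges, by = chunk)) {
        i1 <- min(i0 + chunk - 1L, n_e_edges)
        flags[i0:i1] <- runif(i1 - i0 + 1L) < params$p_e
      }
    }
    if (n_edges > n_e_edges) {
      for (i0 in seq(n_e_edges + 1L, n_edges, by = chunk)) {
        i1 <- min(i0 + chunk - 1L, n_edges)
        flags[i0:i1] <- runif(i1 - i0 + 1L) < params$p_i
      }
    }
  })
  flags
}

#' Effective synaptic parameters of an (un)ensheathed synapse
#'
#' Applies the linear effective-astrocyte mapping
#' `J -> J * (1 - s_en)`, `tau -> tau * (1 - s_en)` to flagged synapses
#' (identity otherwise), optionally restricted to one parameter by the
#' variant mode. Vectorized over `ensheathed`.
#'
#' @param j_base baseline synaptic weight (mV).
#' @param tau_base baseline synaptic time constant (ms).
#' @param s_en ensheathment strength in `[0, 1)`.
#' @param ensheathed logical indicator(s).
#' @param mode variant mode, see [variant_mode()].
#' @return list with `j_eff` and `tau_eff`.
#' @export
#' @examples
#' effective_params(12.5, 5, 0.5, TRUE)
effective_params <- function(j_base, tau_base, s_en, ensheathed,
                             mode = "both") {
  if (s_en < 0 || s_en >= 1) stopf("s_en must lie in [0, 1), got %g", s_en)
  vm <- variant_mode(mode)
  fj <- if (vm$scale_j) 1 - s_en * ensheathed else rep(1, length(ensheathed))
  ft <- if (vm$scale_tau) 1 - s_en * ensheathed else rep(1, length(ensheathed))
  list(j_eff = j_base * fj, tau_eff = tau_base * ft)
}

#' Naive mean-field ensheathment strength
#'
#' The homogeneous surrogate obtained by averaging the ensheathment effect
#' over synapses: every synapse scaled by `s_en * p` instead of a fraction
#' `p` scaled by `s_en`. Heterogeneous networks along an isoline of this
#' quantity behave very differently, which is what makes the naive mean
#' field fail.
#'
#' @param s_en ensheathment strength.
#' @param p ensheathment probability.
#' @return `s_en * p`.
#' @export
naive_mean_field_strength <- function(s_en, p) {
  s_en * p
}
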