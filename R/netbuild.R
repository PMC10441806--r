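#' Parameters of the EIF balanced-network models
#'
#' Bundles the neuron, synapse, connectivity and drive parameters of the
#' exponential integrate-and-fire network, with defaults reproducing the
#' reference parameter set of the non-spatial (`model = "nonspatial"`) or
#' spatially extended (`model = "spatial"`) configuration. Named vectors
#' are indexed by population (`e`, `i`); `k_out` and `j` are 2x2 matrices
#' indexed `[target, source]` -- `k_out[a, b]` is the exact number of
#' outgoing connections each population-`b` neuron makes onto population
#' `a`, and `j[a, b]` the corresponding synaptic weight in mV (positive
#' for excitatory sources, negative for inhibitory).
#'
#' The spatial feedforward weights (`j_ffwd`) and out-degrees
#' (`k_out_ffwd`) are calibration constants of this package: with
#' `j_ffwd = c(140, 100)` mV, the out-degrees are chosen so the mean
#' feedforward drive (in-degree times `j_ffwd/sqrt(N)` times `r_f`) puts
#' the default spatial network's excitatory rate near 5 Hz, comparable to
#' the non-spatial model. They are exposed here precisely because they
#' are calibrations, not canonical values.
#'
#' @param ... the model variant (`"nonspatial"`, the default, or
#'   `"spatial"`) as an optional first unnamed argument, followed by named
#'   overrides of any default field.
#' @param model the model variant, as an explicit alternative to the
#'   unnamed first argument.
#' @return a `network_params` object.
#' @export
#' @examples
#' p <- network_params()
#' p$k_out["e", "e"]
network_params <- function(..., model = c("nonspatial", "spatial")) {
  over <- list(...)
  nm <- names(over) %||% rep("", length(over))
  if (length(over) && identical(nm[1], "")) {
    model <- over[[1]]
    over <- over[-1]
    nm <- nm[-1]
  }
  if (any(nm == "")) stopf("field overrides must be named")
  model <- match.arg(model)
  pops <- c("e", "i")
  p <- list(
    model = model,
    n_e = if (model == "spatial") 40000L else 10000L,
    n_i = 10000L,
    n_f = if (model == "spatial") 5625L else 0L,
    tau_m = c(e = 15, i = 10),
    v_th = -10, v_t = -50, e_l = -60, v_re = -65,
    tau_ref = c(e = 1.5, i = 0.5),
    tau_syn = if (model == "spatial") c(e = 6, i = 5) else c(e = 5, i = 4),
    delta_t = c(e = 2, i = 0.5),
    tau_s = if (model == "spatial") NA_real_ else 40,
    m = if (model == "spatial") c(e = NA_real_, i = NA_real_) else c(e = 0.015, i = 0.01),
    sigma_s = if (model == "spatial") NA_real_ else 0.1,
    r_f = if (model == "spatial") 5 else NA_real_,
    k_out = if (model == "spatial") {
      matrix(c(2000L, 500L, 2000L, 500L), 2, 2, dimnames = list(pops, pops))
    } else {
      matrix(2500L, 2, 2, dimnames = list(pops, pops))
    },
    j = if (model == "spatial") {
      matrix(c(40, 120, -400, -400), 2, 2, dimnames = list(pops, pops))
    } else {
      matrix(c(12.5, 20, -50, -50), 2, 2, dimnames = list(pops, pops))
    },
    j_ffwd = if (model == "spatial") c(e = 140, i = 100) else c(e = NA_real_, i = NA_real_),
    k_out_ffwd = if (model == "spatial") c(e = 12000L, i = 1400L) else c(e = 0L, i = 0L),
    alpha_rec = if (model == "spatial") 0.05 else NA_real_,
    alpha_ffwd = if (model == "spatial") 0.1 else NA_real_
  )
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stopf("unknown network_params field(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  # normalize labels so overrides may pass bare matrices/vectors
  dimnames(p$k_out) <- dimnames(p$j) <- list(pops, pops)
  for (f in c("tau_m", "tau_ref", "tau_syn", "delta_t", "m", "j_ffwd", "k_out_ffwd")) {
    names(p[[f]]) <- pops
  }
  validate_network_params(structure(p, class = "network_params"))
}

validate_network_params <- function(p) {
  if (any(p$j[, "e"] <= 0) || any(p$j[, "i"] >= 0)) {
    stopf("excitatory weights must be positive and inhibitory negative")
  }
  if (p$k_out["e", "e"] > p$n_e || p$k_out["e", "i"] > p$n_e ||
      p$k_out["i", "e"] > p$n_i || p$k_out["i", "i"] > p$n_i) {
    stopf("out-degree k_out[a, b] cannot exceed the size of target population a")
  }
  p
}

#' Scale a network down while preserving its connectivity regime
#'
#' Multiplies the population sizes and out-degrees by `scale` (rounded;
#' snapped to perfect squares for the spatial grids) and leaves the weight
#' parameters untouched -- the `1/sqrt(N)` coupling normalization adapts
#' automatically, so the scaled network stays in the dense, strongly
#' coupled regime.
#'
#' @param params a [network_params()].
#' @param scale factor in `(0, 1]`.
#' @return a rescaled `network_params`.
#' @export
scale_network_params <- function(params, scale) {
  stopifnot(inherits(params, "network_params"), scale > 0, scale <= 1)
  p <- params
  if (p$model == "spatial") {
    p$n_e <- as.integer(round(sqrt(p$n_e * scale))^2)
    p$n_i <- as.integer(round(sqrt(p$n_i * scale))^2)
    p$n_f <- as.integer(round(sqrt(p$n_f * scale))^2)
  } else {
    p$n_e <- as.integer(round(p$n_e * scale))
    p$n_i <- as.integer(round(p$n_i * scale))
  }
  p$k_out[] <- as.integer(round(p$k_out * scale))
  p$k_out_ffwd[] <- as.integer(round(p$k_out_ffwd * scale))
  validate_network_params(p)
}

# ---- connectivity ----------------------------------------------------------

new_connectivity <- function(model, n_e, n_i, n_f, pre_ptr, post,
                             ffwd_ptr = NULL, ffwd_post = NULL,
                             positions = NULL, positions_f = NULL, seed = NA) {
  structure(list(model = model, n_e = as.integer(n_e), n_i = as.integer(n_i),
                 n_f = as.integer(n_f), pre_ptr = pre_ptr, post = post,
                 ffwd_ptr = ffwd_ptr, ffwd_post = ffwd_post,
                 positions = positions, positions_f = positions_f,
                 seed = seed),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("%s connectivity: %d E + %d I neurons, %d recurrent edges",
              x$model, x$n_e, x$n_i, length(x$post)))
  if (x$n_f > 0) cat(sprintf(", %d ffwd neurons (%d ffwd edges)", x$n_f, length(x$ffwd_post)))
  cat("\n")
  invisible(x)
}

# number of out-edges per presynaptic neuron
edge_counts <- function(conn) diff(conn$pre_ptr)

# TRUE for edges whose presynaptic neuron is excitatory
edge_pre_pop_e <- function(conn) {
  n <- conn$n_e + conn$n_i
  rep(seq_len(n) <= conn$n_e, edge_counts(conn))
}

#' Recurrent edges of a connectivity as a tibble
#'
#' @param conn a `connectivity`.
#' @return tibble with `pre`, `post`, `pre_pop`, `post_pop`.
#' @export
edge_table <- function(conn) {
  stopifnot(inherits(conn, "connectivity"))
  n <- conn$n_e + conn$n_i
  pre <- rep(seq_len(n), edge_counts(conn))
  tibble(pre = pre, post = conn$post,
         pre_pop = ifelse(pre <= conn$n_e, "e", "i"),
         post_pop = ifelse(conn$post <= conn$n_e, "e", "i"))
}

# sample k of n without replacement, excluding index `self` (0 = none);
# sorted for cache-friendly spike delivery
sample_excl <- function(n, k, self = 0L) {
  if (self == 0L) {
    if (k > n) stopf("out-degree %d exceeds target population size %d", k, n)
    sort.int(sample.int(n, k), method = "radix")
  } else {
    if (k > n - 1L) stopf("out-degree %d exceeds target population size %d (self excluded)", k, n - 1L)
    s <- sample.int(n - 1L, k)
    sort.int(s + (s >= self), method = "radix")
  }
}

#' Build non-spatial fixed-out-degree random connectivity
#'
#' Every presynaptic neuron of population `b` sends exactly `k_out[a, b]`
#' edges to distinct, uniformly chosen neurons of population `a`
#' (self-connections excluded, no duplicates).
#'
#' @param params a [network_params()] (`model = "nonspatial"`).
#' @param seed integer seed; the graph is a pure function of
#'   `(params, seed)`.
#' @return a `connectivity`.
#' @export
build_nonspatial <- function(params, seed = 1) {
  stopifnot(inherits(params, "network_params"))
  n_e <- params$n_e
  n_i <- params$n_i
  n <- n_e + n_i
  k <- params$k_out
  with_seed(seed, {
    posts <- vector("list", n)
    for (pre in seq_len(n)) {
      b <- if (pre <= n_e) "e" else "i"
      te <- sample_excl(n_e, k["e", b], if (b == "e") pre else 0L)
      ti <- sample_excl(n_i, k["i", b], if (b == "i") pre - n_e else 0L) + n_e
      posts[[pre]] <- c(te, ti)
    }
  })
  post <- unlist(posts, use.names = FALSE)
  ptr <- c(0L, cumsum(lengths(posts)))
  new_connectivity("nonspatial", n_e, n_i, 0L, ptr, post, seed = seed)
}

#' Wrapped Gaussian density on the unit circle
#'
#' `g(u; alpha) = sum_k N(u + k; 0, alpha^2)` over integer wraps `k`,
#' truncated where terms fall below 1e-12. Periodic with period 1 and
#' normalized on `[0, 1]`; the distance-dependent connection profile of the
#' spatial model.
#'
#' @param u evaluation points (any real; the density is periodic).
#' @param alpha width parameter, `> 0`.
#' @return density values.
#' @export
wrapped_gaussian <- function(u, alpha) {
  if (alpha <= 0) stopf("alpha must be positive, got %g", alpha)
  K <- as.integer(ceiling(8 * alpha)) + 1L
  ks <- seq(-K, K)
  rowSums(outer(u, ks, function(a, b) dnorm(a + b, 0, alpha)))
}

#' Periodic (torus) distance on the unit square
#'
#' Euclidean distance with per-coordinate wrap-around
#' `min(|d|, 1 - |d|)`. Accepts length-2 vectors or n x 2 matrices
#' (rows paired, with single rows recycled).
#'
#' @param x,y points in `[0, 1]^2`.
#' @return numeric distance(s).
#' @export
#' @examples
#' torus_distance(c(0, 0), c(0.9, 0)) # 0.1
torus_distance <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (is.null(dim(y))) y <- matrix(y, ncol = 2)
  if (nrow(x) == 1 && nrow(y) > 1) x <- x[rep(1, nrow(y)), , drop = FALSE]
  if (nrow(y) == 1 && nrow(x) > 1) y <- y[rep(1, nrow(x)), , drop = FALSE]
  d <- abs(x - y)
  d <- pmin(d, 1 - d)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# positions of a side x side grid, normalized to the unit torus
grid_positions <- function(side, origin = c(0, 0)) {
  ix <- (seq_len(side^2) - 1L) %% side
  iy <- (seq_len(side^2) - 1L) %/% side
  cbind((ix / side + origin[1]) %% 1, (iy / side + origin[2]) %% 1)
}

# snap torus points to the nearest site of a grid with given side/origin;
# returns 1-based grid indices
snap_to_grid <- function(px, py, side, origin = c(0, 0)) {
  ix <- round(((px - origin[1]) %% 1) * side) %% side
  iy <- round(((py - origin[2]) %% 1) * side) %% side
  as.integer(iy * side + ix + 1L)
}

# sample k wrapped-Gaussian displaced contacts per presynaptic neuron;
# returns a k x n_pre matrix of 1-based target indices in the target grid
sample_contacts <- function(pre_pos, k, alpha, side, origin = c(0, 0)) {
  n_pre <- nrow(pre_pos)
  total <- n_pre * k
  px <- rep(pre_pos[, 1], each = k) + rnorm(total, 0, alpha)
  py <- rep(pre_pos[, 2], each = k) + rnorm(total, 0, alpha)
  matrix(snap_to_grid(px, py, side, origin), nrow = k)
}

#' Build spatial (torus) connectivity with wrapped-Gaussian profiles
#'
#' Neurons are arranged on uniform grids covering the unit torus. Each
#' presynaptic neuron draws its `k_out[a, b]` contacts by sampling 2D
#' displacements from an isotropic Gaussian of width `alpha_rec`
#' (`alpha_ffwd` for the feedforward layer), wrapping periodically, and
#' snapping to the nearest grid site of the target population; multiple
#' contacts onto one target are kept with multiplicity. The expected
#' number of contacts from a neuron at `y` onto one at `x` is then
#' `(k_out[a, b] / N_a) * g(x1 - y1; alpha) * g(x2 - y2; alpha)` with `g`
#' the [wrapped_gaussian()].
#'
#' @param params a [network_params()] (`model = "spatial"`); population
#'   sizes must be perfect squares.
#' @param seed integer seed.
#' @param origin torus offset of all grids (useful for testing translation
#'   invariance).
#' @return a `connectivity` with positions and a feedforward layer.
#' @export
build_spatial <- function(params, seed = 1, origin = c(0, 0)) {
  stopifnot(inherits(params, "network_params"))
  side_e <- sqrt(params$n_e)
  side_i <- sqrt(params$n_i)
  side_f <- sqrt(params$n_f)
  if (side_e != round(side_e) || side_i != round(side_i) ||
      (params$n_f > 0 && side_f != round(side_f))) {
    stopf("spatial population sizes must be perfect squares (got %d, %d, %d)",
          params$n_e, params$n_i, params$n_f)
  }
  pos_e <- grid_positions(side_e, origin)
  pos_i <- grid_positions(side_i, origin)
  k <- params$k_out

  # fill a preallocated edge vector in presynaptic chunks (memory stays
  # bounded at reference network sizes); per presynaptic neuron the E
  # targets precede the I targets
  fill_block <- function(post, pos_pre, k_e, k_i, alpha, start, chunk = 2000L) {
    n_pre <- nrow(pos_pre)
    k_tot <- k_e + k_i
    for (c0 in seq(1L, n_pre, by = chunk)) {
      c1 <- min(c0 + chunk - 1L, n_pre)
      pc <- pos_pre[c0:c1, , drop = FALSE]
      m <- matrix(0L, k_tot, nrow(pc))
      if (k_e > 0) m[seq_len(k_e), ] <- sample_contacts(pc, k_e, alpha, side_e, origin)
      if (k_i > 0) {
        m[k_e + seq_len(k_i), ] <-
          sample_contacts(pc, k_i, alpha, side_i, origin) + params$n_e
      }
      idx <- start + (c0 - 1L) * k_tot
      post[idx:(idx + length(m) - 1L)] <- m
    }
    post
  }

  with_seed(seed, {
    post <- integer(params$n_e * (k["e", "e"] + k["i", "e"]) +
                      params$n_i * (k["e", "i"] + k["i", "i"]))
    post <- fill_block(post, pos_e, k["e", "e"], k["i", "e"], params$alpha_rec, 1L)
    post <- fill_block(post, pos_i, k["e", "i"], k["i", "i"], params$alpha_rec,
                       1L + params$n_e * (k["e", "e"] + k["i", "e"]))
    ptr <- c(0L, cumsum(c(rep(k["e", "e"] + k["i", "e"], params$n_e),
                          rep(k["e", "i"] + k["i", "i"], params$n_i))))
    if (params$n_f > 0) {
      pos_f <- grid_positions(side_f, origin)
      ffwd_post <- integer(params$n_f * sum(params$k_out_ffwd))
      ffwd_post <- fill_block(ffwd_post, pos_f, params$k_out_ffwd[["e"]],
                              params$k_out_ffwd[["i"]], params$alpha_ffwd, 1L)
      ffwd_ptr <- c(0L, cumsum(rep(sum(params$k_out_ffwd), params$n_f)))
    } else {
      pos_f <- NULL
      ffwd_post <- NULL
      ffwd_ptr <- NULL
    }
  })
  new_connectivity("spatial", params$n_e, params$n_i, params$n_f,
                   as.integer(ptr), as.integer(post),
                   ffwd_ptr = if (!is.null(ffwd_ptr)) as.integer(ffwd_ptr),
                   ffwd_post = if (!is.null(ffwd_post)) as.integer(ffwd_post),
                   positions = rbind(pos_e, pos_i), positions_f = pos_f,
                   seed = seed)
}
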