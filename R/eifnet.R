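#' Simulation configuration for the EIF network
#'
#' @param t_total trial length (ms); the reference protocol uses 5 s
#'   trials.
#' @param dt integration step (ms), at most 0.1.
#' @param burn_in initial interval (ms) discarded from all analyses.
#' @param seed_noise seed for the feedforward drive (Gaussian-process
#'   realizations or Poisson layer spikes).
#' @param seed_init seed for initial membrane potentials, drawn uniformly
#'   on `[V_re, V_T]`.
#' @param record_currents_for neuron ids whose input currents are recorded.
#' @param record_voltage also record membrane potential for those neurons.
#' @param record_dt sampling interval for recorded traces (ms).
#' @param max_rate_hz spike budget: if the network-average rate implied by
#'   the running spike count exceeds this, the run stops early and is
#'   flagged truncated (an unstable, runaway-excitation realization).
#' @return a `sim_config`.
#' @export
sim_config <- function(t_total = 5000, dt = 0.05, burn_in = 500,
                       seed_noise = 1, seed_init = 2,
                       record_currents_for = integer(0),
                       record_voltage = FALSE, record_dt = 0.5,
                       max_rate_hz = 60) {
  if (dt > 0.1) stopf("dt must be <= 0.1 ms, got %g", dt)
  if (burn_in >= t_total) stopf("burn_in must be shorter than t_total")
  structure(list(t_total = t_total, dt = dt, burn_in = burn_in,
                 seed_noise = as.integer(seed_noise),
                 seed_init = as.integer(seed_init),
                 record_currents_for = as.integer(record_currents_for),
                 record_voltage = record_voltage, record_dt = record_dt,
                 max_rate_hz = max_rate_hz),
            class = "sim_config")
}

#' Feedforward drive specifications
#'
#' Three drive kinds: `shared_noise_drive()` gives every neuron the static
#' bias `sqrt(N) * m_a` plus one shared Gaussian-process realization
#' `sigma_s * s(t)` with squared-exponential autocovariance
#' `cov(s(t), s(t + tau)) = exp(-tau^2 / tau_s^2)`;
#' `two_population_drive()` randomly splits the network in half, each half
#' receiving its own independent realization; `poisson_drive()` drives the
#' network through the spatial model's feedforward layer of
#' Poisson-spiking neurons. Drive parameters (`m`, `sigma_s`, `tau_s`,
#' `r_f`, `j_ffwd`) are taken from the [network_params()] at simulation
#' time.
#'
#' @return a `feedforward_drive` specification.
#' @export
shared_noise_drive <- function() {
  structure(list(kind = "shared_noise"), class = "feedforward_drive")
}

#' @rdname shared_noise_drive
#' @param seed_split optional dedicated seed for the half/half group
#'   assignment; defaults to a seed derived from the drive seed.
#' @export
two_population_drive <- function(seed_split = NULL) {
  structure(list(kind = "two_population_noise", seed_split = seed_split),
            class = "feedforward_drive")
}

#' @rdname shared_noise_drive
#' @export
poisson_drive <- function() {
  structure(list(kind = "poisson_layer"), class = "feedforward_drive")
}

#' Sample the shared Gaussian-process noise
#'
#' Generates a stationary, zero-mean, unit-variance Gaussian process with
#' autocovariance `exp(-tau^2 / tau_s^2)` on the integration grid, by
#' circular convolution of white noise with a Gaussian kernel of standard
#' deviation `tau_s / 2` (the kernel's self-convolution then has exactly
#' the target width) and exact variance normalization.
#'
#' @param t_total trace length (ms).
#' @param dt sample spacing (ms).
#' @param tau_s correlation timescale (ms).
#' @param seed integer seed.
#' @return numeric vector of length `round(t_total / dt)`.
#' @export
sample_shared_noise <- function(t_total, dt, tau_s, seed = 1) {
  stopifnot(tau_s > 0, dt > 0)
  n <- round(t_total / dt)
  w <- with_seed(seed, rnorm(n))
  sigma_k <- tau_s / 2
  half <- min(ceiling(6 * sigma_k / dt), floor((n - 1) / 2))
  k <- dnorm(seq(-half, half) * dt, sd = sigma_k)
  kern <- numeric(n)
  kern[1:(half + 1)] <- k[(half + 1):(2 * half + 1)]
  if (half > 0) kern[n - seq_len(half) + 1] <- k[half:1]
  s <- Re(fft(fft(w) * fft(kern), inverse = TRUE)) / n
  s / sqrt(sum(kern^2))
}

#' Generate the Poisson feedforward raster
#'
#' Independent homogeneous Poisson spike trains at rate `r_f` per neuron.
#'
#' @param n_f number of feedforward neurons.
#' @param r_f rate (Hz).
#' @param t_total duration (ms).
#' @param seed integer seed.
#' @return a [spike_raster()] with `pop = "f"` labels.
#' @export
generate_poisson_ffwd <- function(n_f, r_f, t_total, seed = 1) {
  stopifnot(r_f >= 0)
  with_seed(seed, {
    counts <- rpois(n_f, r_f * t_total / 1000)
    times <- runif(sum(counts), 0, t_total)
  })
  neuron <- rep(seq_len(n_f), counts)
  ord <- order(times)
  spike_raster(neuron[ord], times[ord], n_f, pop = rep("f", n_f),
               t_end = t_total)
}

#' Integral of the synaptic kernel
#'
#' The synaptic kernel `eta(t) = (1/tau) exp(-t/tau) H(t)` integrates to 1
#' for every `tau`, so scaling `tau` changes only the kinetics and not the
#' total transferred charge. With `dt` supplied, returns the discrete-sum
#' charge of the Euler-discretized filter (decay factor `1 - dt/tau`,
#' initial value `1/tau`), which equals 1 exactly in the infinite-horizon
#' limit and `1 - (1 - dt/tau)^m` over `m` steps.
#'
#' @param tau synaptic time constant (ms), `> 0`.
#' @param dt optional integration step (ms) for the discrete filter.
#' @param t_max horizon for the discrete sum (ms).
#' @return the kernel integral.
#' @export
kernel_integral <- function(tau, dt = NULL, t_max = Inf) {
  stopifnot(tau > 0)
  if (is.null(dt)) {
    return(1)
  }
  stopifnot(dt > 0, dt < tau)
  if (!is.finite(t_max)) {
    return(1)
  }
  m <- floor(t_max / dt)
  1 - (1 - dt / tau)^m
}

# ---- network compilation ---------------------------------------------------

# Mean-field balance solution of the scaled network: population rates
# (kHz) solving K_in %*% (J_eff/sqrt(N)) r + F = 0, with J_eff the
# ensheathment-averaged weights. Returns NULL when the system is singular
# or the solution is not a pair of positive rates (e.g., degenerate test
# networks), in which case callers fall back to zero initial filters.
balance_rates <- function(params, ens, drive_mean) {
  n <- c(params$n_e, params$n_i)
  if (any(n == 0)) {
    return(NULL)
  }
  k_in <- params$k_out * matrix(n, 2, 2, byrow = TRUE) / matrix(n, 2, 2)
  f_ens <- 1 - ens$s_en * variant_mode(ens$mode)$scale_j *
    c(ens$p_e, ens$p_i)
  j_eff <- params$j * matrix(f_ens, 2, 2, byrow = TRUE)
  a <- k_in * j_eff / sqrt(sum(n))
  r <- tryCatch(solve(a, -drive_mean), error = function(e) NULL)
  if (is.null(r) || !all(is.finite(r)) || any(r < 0)) {
    return(NULL)
  }
  r
}

# Stationary filter statistics per (class, target population): a filter
# of class c (source pop b, time constant tau_c) receiving Poisson
# increments of size j_eff/(tau_c*sqrt(N)) at rate
# lambda = K_in[a,b] * frac_c * r_b has mean lambda * j_eff / sqrt(N)
# (Campbell's theorem; the tau cancels) and variance
# lambda * j_eff^2 / (2 * tau_c * N).
stationary_filters <- function(params, ens, rates, n_classes = 5L,
                               ffwd_rate_khz = 0, in_deg_f = c(0, 0)) {
  mean_m <- matrix(0, n_classes, 2)
  sd_m <- matrix(0, n_classes, 2)
  if (is.null(rates)) {
    return(list(mean = mean_m, sd = sd_m))
  }
  cl <- compile_classes(params, ens)
  n <- c(params$n_e, params$n_i)
  n_tot <- sum(n)
  k_in <- params$k_out * matrix(n, 2, 2, byrow = TRUE) / matrix(n, 2, 2)
  f_j <- if (variant_mode(ens$mode)$scale_j) 1 - ens$s_en else 1
  p <- c(ens$p_e, ens$p_i)
  for (b in 1:2) {
    for (ens_state in 0:1) {
      cls <- (b - 1L) * 2L + ens_state + 1L
      frac <- if (ens_state == 1) p[b] else 1 - p[b]
      jj <- params$j[, b] * (if (ens_state == 1) f_j else 1)
      lambda <- k_in[, b] * frac * rates[b]
      mean_m[cls, ] <- lambda * jj / sqrt(n_tot)
      sd_m[cls, ] <- sqrt(lambda * jj^2 / (2 * cl$tau[cls] * n_tot))
    }
  }
  if (ffwd_rate_khz > 0) {
    lambda_f <- in_deg_f * ffwd_rate_khz
    jf <- unname(params$j_ffwd)
    mean_m[5, ] <- lambda_f * jf / sqrt(n_tot)
    sd_m[5, ] <- sqrt(lambda_f * jf^2 / (2 * cl$tau[5] * n_tot))
  }
  list(mean = mean_m, sd = sd_m)
}

# Filter classes: 1 = E unensheathed, 2 = E ensheathed, 3 = I unensheathed,
# 4 = I ensheathed, 5 = feedforward (excitatory kernel, never ensheathed).
compile_classes <- function(params, ens) {
  vm <- variant_mode(ens$mode)
  ft <- if (vm$scale_tau) 1 - ens$s_en else 1
  tau_e <- unname(params$tau_syn["e"])
  tau_i <- unname(params$tau_syn["i"])
  list(tau = c(tau_e, tau_e * ft, tau_i, tau_i * ft, tau_e),
       comp = c(1L, 1L, 2L, 2L, 0L),
       f_j = if (vm$scale_j) 1 - ens$s_en else 1)
}

# per-edge class ids (0-based) and filter increments
# j_eff/(tau_class*sqrt(N)); compiled in C++ to stay memory-lean at
# reference network sizes
compile_edges <- function(conn, params, ens, flags) {
  cl <- compile_classes(params, ens)
  ce <- compile_edges_cpp(conn$pre_ptr, conn$post, conn$n_e, flags,
                          params$j, cl$tau, cl$f_j,
                          sqrt(conn$n_e + conn$n_i))
  list(cls0 = ce$cls, winc = ce$winc, classes = cl)
}

#' Sample neurons for current/correlation recording
#'
#' @param conn a `connectivity`.
#' @param n how many neurons.
#' @param seed dedicated sampling seed.
#' @param pop population to sample from (default excitatory).
#' @return sorted integer ids.
#' @export
sample_record_ids <- function(conn, n, seed = 1, pop = "e") {
  ids <- if (pop == "e") seq_len(conn$n_e) else conn$n_e + seq_len(conn$n_i)
  sort(with_seed(seed, sample(ids, min(n, length(ids)))))
}

#' Simulate the heterogeneous EIF network
#'
#' Forward-Euler integration of the exponential integrate-and-fire network
#' `dV/dt = -(V - E_L)/tau_m + (Delta_T/tau_m) exp((V - V_T)/Delta_T) + F + R`
#' with spike-and-reset at `V_th`, refractory holding at `V_re`, and
#' class-based exponential synaptic filtering: each neuron keeps one filter
#' state per (source population x ensheathment state) class, so the
#' per-synapse heterogeneity introduced by the effective astrocyte costs at
#' most four recurrent filters per neuron. A presynaptic spike delivers
#' total integrated input `j_eff / sqrt(N)` mV through its class filter.
#'
#' With `s_en = 0` the run is event-for-event identical to the default
#' (astrocyte-free) network under the same seeds.
#'
#' @param conn a `connectivity`.
#' @param params the matching [network_params()].
#' @param ens an [ensheathment_params()]; flags are assigned internally
#'   from its seed (identical across variant modes).
#' @param drive a feedforward drive specification, see
#'   [shared_noise_drive()].
#' @param cfg a [sim_config()].
#' @return list with `raster` (a [spike_raster()]) and `currents` (a
#'   `current_record` with `time`, `ffwd`, `rec_e`, `rec_i` trace matrices
#'   in mV/ms, or `NULL` if nothing was recorded).
#' @export
simulate_network <- function(conn, params, ens = ensheathment_params(0),
                             drive = shared_noise_drive(),
                             cfg = sim_config()) {
  stopifnot(inherits(conn, "connectivity"), inherits(params, "network_params"),
            inherits(ens, "ensheathment_params"),
            inherits(drive, "feedforward_drive"), inherits(cfg, "sim_config"))
  n_e <- conn$n_e
  n_i <- conn$n_i
  n <- n_e + n_i
  n_steps <- round(cfg$t_total / cfg$dt)

  # with s_en = 0 the ensheathed classes are identical to the baseline
  # ones; collapsing them (flags and stationary filters alike) guarantees
  # bitwise identity with the default run
  ens_c <- if (ens$s_en == 0) ensheathment_params(0, seed = ens$seed) else ens
  flags <- if (ens$s_en == 0) {
    logical(length(conn$post))
  } else {
    assign_ensheathment(conn, ens)
  }
  ce <- compile_edges(conn, params, ens_c, flags)
  rm(flags)

  # feedforward drive
  group <- integer(n)
  noise <- matrix(numeric(0), 0, 0)
  sigma_s <- 0
  bias <- numeric(2) # per population (e, i)
  ffwd_ptr <- 0L
  ffwd_target <- integer(0)
  ffwd_class <- integer(0)
  ffwd_winc <- numeric(0)
  ffwd_step <- integer(0)
  ffwd_id <- integer(0)
  if (drive$kind %in% c("shared_noise", "two_population_noise")) {
    if (!is.finite(params$tau_s) || !all(is.finite(params$m))) {
      stopf("noise drive needs finite tau_s and m in network_params")
    }
    n_groups <- if (drive$kind == "two_population_noise") 2L else 1L
    noise <- vapply(seq_len(n_groups), function(g) {
      sample_shared_noise(cfg$t_total, cfg$dt, params$tau_s,
                          derive_seed(cfg$seed_noise, "gp", g))
    }, numeric(n_steps))
    sigma_s <- params$sigma_s
    if (n_groups == 2L) {
      seed_split <- drive$seed_split %||% derive_seed(cfg$seed_noise, "split")
      perm <- with_seed(seed_split, sample.int(n))
      group[perm[seq_len(floor(n / 2))]] <- 1L
    }
    bias <- sqrt(n) * unname(params$m)
  } else { # poisson_layer
    if (is.null(conn$ffwd_ptr) || conn$n_f == 0) {
      stopf("poisson_layer drive requires a connectivity with a feedforward layer")
    }
    if (!is.finite(params$r_f) || !all(is.finite(params$j_ffwd))) {
      stopf("poisson_layer drive needs finite r_f and j_ffwd in network_params")
    }
    fr <- generate_poisson_ffwd(conn$n_f, params$r_f, cfg$t_total,
                                derive_seed(cfg$seed_noise, "poisson"))
    step <- pmin(floor(fr$events$time / cfg$dt), n_steps - 1L)
    ord <- order(step)
    ffwd_step <- as.integer(step[ord])
    ffwd_id <- fr$events$neuron[ord] - 1L
    ffwd_ptr <- conn$ffwd_ptr
    ffwd_target <- conn$ffwd_post
    post_idx <- ifelse(conn$ffwd_post <= n_e, 1L, 2L)
    tau_f <- ce$classes$tau[5]
    ffwd_winc <- unname(params$j_ffwd)[post_idx] / (tau_f * sqrt(n))
    ffwd_class <- rep(4L, length(ffwd_target)) # 0-based class 5
  }

  v0 <- with_seed(cfg$seed_init, runif(n, params$v_re, params$v_t))
  record_stride <- max(1L, as.integer(round(cfg$record_dt / cfg$dt)))
  max_spikes <- cfg$max_rate_hz * n * cfg$t_total / 1000

  # Start the synaptic filters inside the stationary balanced state:
  # per-neuron values drawn around the mean-field stationary mean with the
  # shot-noise standard deviation. Zero-filter starts leave the network
  # transiently without recurrent inhibition, and mean-only starts leave
  # it without the input fluctuations that sustain firing -- both can
  # lock desk-scale runs into spurious onset volleys.
  if (drive$kind == "poisson_layer") {
    in_deg_f <- conn$n_f * unname(params$k_out_ffwd) / c(n_e, n_i)
    drive_mean <- in_deg_f * unname(params$j_ffwd) / sqrt(n) * params$r_f / 1000
    ffwd_rate_khz <- params$r_f / 1000
  } else {
    in_deg_f <- c(0, 0)
    drive_mean <- bias
    ffwd_rate_khz <- 0
  }
  sf <- stationary_filters(params, ens_c, balance_rates(params, ens_c, drive_mean),
                           ffwd_rate_khz = ffwd_rate_khz, in_deg_f = in_deg_f)
  pop_col <- c(rep(1L, n_e), rep(2L, n_i))
  x0 <- sf$mean[, pop_col, drop = FALSE] +
    matrix(with_seed(derive_seed(cfg$seed_init, "filters"), rnorm(5L * n)),
           5L, n) * sf$sd[, pop_col, drop = FALSE]

  res <- eif_sim_cpp(
    edge_ptr = conn$pre_ptr, edge_target = conn$post,
    edge_class = ce$cls0, edge_winc = ce$winc,
    ffwd_ptr = ffwd_ptr, ffwd_target = ffwd_target,
    ffwd_class = ffwd_class, ffwd_winc = ffwd_winc,
    ffwd_spike_step = ffwd_step, ffwd_spike_id = ffwd_id,
    class_tau = ce$classes$tau, class_comp = ce$classes$comp,
    noise = noise, group = group, bias = bias, sigma_s = sigma_s,
    n_e = n_e,
    tau_m = unname(params$tau_m), v_th = rep(params$v_th, 2),
    v_t = rep(params$v_t, 2), e_l = rep(params$e_l, 2),
    v_re = rep(params$v_re, 2), delta_t = unname(params$delta_t),
    ref_steps = as.integer(round(unname(params$tau_ref) / cfg$dt)),
    v0 = v0, dt = cfg$dt, n_steps = n_steps,
    record_ids = cfg$record_currents_for - 1L,
    record_stride = record_stride, record_v = cfg$record_voltage,
    max_spikes = max_spikes,
    active_classes = sort(unique(c(ce$cls0, ffwd_class))), x0 = x0)

  raster <- spike_raster(res$spike_id, res$spike_time, n,
                         pop = c(rep("e", n_e), rep("i", n_i)),
                         group = group + 1L, positions = conn$positions,
                         t_end = res$t_end, truncated = res$truncated)
  currents <- NULL
  if (!is.null(res$currents)) {
    cc <- res$currents
    keep <- seq_len(cc$n_samples)
    currents <- structure(list(
      time = cc$time[keep],
      ffwd = cc$ffwd[keep, , drop = FALSE],
      rec_e = cc$rec_e[keep, , drop = FALSE],
      rec_i = cc$rec_i[keep, , drop = FALSE],
      voltage = if (cfg$record_voltage) cc$voltage[keep, , drop = FALSE],
      ids = cfg$record_currents_for,
      pop = c(rep("e", n_e), rep("i", n_i))[cfg$record_currents_for],
      dt_sample = cfg$dt * record_stride), class = "current_record")
  }
  list(raster = raster, currents = currents)
}
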