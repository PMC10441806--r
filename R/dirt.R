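#' Configuration for the microscale diffusion-with-recharging-traps model
#'
#' Defines the idealized 2D synaptic cleft in which released
#' neurotransmitter molecules diffuse until captured by a postsynaptic
#' receptor or by the ensheathing astrocyte. The cleft is the rectangle
#' `[0, c_w] x [0, c_h]`; `n_rec` equally sized receptors tile the
#' postsynaptic density interval `psd` on the bottom boundary; two
#' perfectly absorbing astrocyte walls sit at `x = c_w*phi/2` and
#' `x = c_w*(1 - phi/2)`. Positive `phi` protrudes into the cleft;
#' negative `phi` leaves an extracellular pocket outside each cleft
#' mouth, wrapped by the astrocyte flush along the terminal membranes
#' (absorbing outer wall and ceiling, reflecting floor), which makes the
#' escape statistics independent of the wall distance once the gap
#' exceeds the cleft height. Defaults are the model's reference parameter
#' set (arbitrary units).
#'
#' @param n_nt number of neurotransmitter molecules released at
#'   `(c_w/2, c_h)`.
#' @param n_rec number of receptors along the postsynaptic density.
#' @param tau_r mean receptor recharge time; after a capture the receptor
#'   reflects for an Exp(`tau_r`) time.
#' @param k_abs receptor absorption rate; the per-contact capture
#'   probability is `k_abs * sqrt(pi * dt_diff / d_coef)`.
#' @param d_coef diffusion coefficient.
#' @param c_w,c_h cleft width and height.
#' @param psd interval `[psd1, psd2]` within `[0, c_w]` holding receptors.
#' @param phi fraction of the cleft blocked by the astrocyte, in
#'   `[-1, 0.95]`.
#' @param dt_diff diffusion time step; must satisfy
#'   `sqrt(2 * d_coef * dt_diff) < c_h / 4`.
#' @param t_cap simulation time cap; particles still free at the cap are
#'   tallied separately.
#' @param seed integer seed for the particle simulation.
#' @return a `dirt_config` object.
#' @export
#' @examples
#' cfg <- dirt_config(phi = 0.4)
dirt_config <- function(n_nt = 1000, n_rec = 50, tau_r = 0.1, k_abs = 1,
                        d_coef = 1, c_w = 1, c_h = 0.1,
                        psd = c(0.25, 0.75), phi = 0, dt_diff = 1e-5,
                        t_cap = 200, seed = 1) {
  if (length(psd) != 2 || psd[1] >= psd[2] || psd[1] < 0 || psd[2] > c_w) {
    stopf("psd must be an interval [psd1, psd2] with psd1 < psd2 inside [0, %g]", c_w)
  }
  if (phi >= 1) stopf("phi = %g gives a degenerate (empty) domain; phi < 1 required", phi)
  if (phi < -1 || phi > 0.95) stopf("phi must lie in [-1, 0.95], got %g", phi)
  if (d_coef <= 0 || c_w <= 0 || c_h <= 0 || dt_diff <= 0) {
    stopf("d_coef, c_w, c_h and dt_diff must be positive")
  }
  if (sqrt(2 * d_coef * dt_diff) >= c_h / 4) {
    stopf(paste("dt_diff too coarse: rms step sqrt(2*D*dt) = %g must be below",
                "a quarter of the cleft height (%g)"),
          sqrt(2 * d_coef * dt_diff), c_h / 4)
  }
  if (k_abs < 0) stopf("k_abs must be >= 0")
  structure(list(n_nt = as.integer(n_nt), n_rec = as.integer(n_rec),
                 tau_r = tau_r, k_abs = k_abs, d_coef = d_coef,
                 c_w = c_w, c_h = c_h, psd = psd, phi = phi,
                 dt_diff = dt_diff, t_cap = t_cap, seed = as.integer(seed)),
            class = "dirt_config")
}

#' Simulate neurotransmitter diffusion with recharging receptor traps
#'
#' Runs the Monte-Carlo particle simulation defined by a [dirt_config()]:
#' all molecules are released simultaneously at the top-center of the
#' cleft, perform independent Gaussian steps of per-axis standard deviation
#' `sqrt(2 * d_coef * dt_diff)`, reflect off the top and bottom membranes,
#' are captured with probability `k_abs * sqrt(pi * dt_diff / d_coef)` on
#' contact with a receptor in its absorbing state (which then recharges
#' for an exponential time), and are absorbed on first contact with either
#' astrocyte wall. The synaptic time course is the number of receptors in
#' the activated (recharging) state over time.
#'
#' @param config a [dirt_config()].
#' @return a `dirt_timecourse` object with the capture event times, the
#'   absorption tallies, and the activation curve evaluated on a 0.05-unit
#'   grid (see [active_receptors()] to re-evaluate on another grid).
#' @export
#' @examples
#' tc <- simulate_dirt(dirt_config(n_nt = 100, seed = 7))
#' tc$receptor_absorbed + tc$astro_absorbed + tc$free_at_cap == 100
simulate_dirt <- function(config) {
  stopifnot(inherits(config, "dirt_config"))
  res <- dirt_run_cpp(config$n_nt, config$n_rec, config$tau_r, config$k_abs,
                      config$d_coef, config$c_w, config$c_h,
                      config$psd[1], config$psd[2], config$phi,
                      config$dt_diff, config$t_cap, config$seed)
  t_last <- if (length(res$receptor_recover)) max(res$receptor_recover) else 0
  times <- seq(0, max(t_last, 1e-3), by = 0.05)
  tc <- structure(list(receptor_times = res$receptor_times,
                       receptor_recover = res$receptor_recover,
                       astro_times = res$astro_times,
                       receptor_absorbed = length(res$receptor_times),
                       astro_absorbed = length(res$astro_times),
                       free_at_cap = res$free_at_cap,
                       t_end = res$t_end, config = config),
                  class = "dirt_timecourse")
  tc$times <- times
  tc$active <- active_receptors(tc, times)
  tc
}

#' Evaluate the active-receptor curve of a DiRT run
#'
#' A receptor is active from the moment it captures a molecule until the
#' end of its recharge period; the curve counts active receptors at each
#' requested time.
#'
#' @param tc a `dirt_timecourse` from [simulate_dirt()].
#' @param times numeric vector of evaluation times.
#' @return integer vector of active-receptor counts.
#' @export
active_receptors <- function(tc, times) {
  stopifnot(inherits(tc, "dirt_timecourse"))
  starts <- sort(tc$receptor_times)
  ends <- sort(tc$receptor_recover)
  findInterval(times, starts) - findInterval(times, ends, left.open = TRUE)
}

#' @export
print.dirt_timecourse <- function(x, ...) {
  cat(sprintf(paste0("DiRT time course (phi = %.2f): %d receptor captures, ",
                     "%d astrocyte absorptions, %d free at cap, t_end = %.2f\n"),
              x$config$phi, x$receptor_absorbed, x$astro_absorbed,
              x$free_at_cap, x$t_end))
  invisible(x)
}

#' Summarize a synaptic time course into strength and half-max width
#'
#' The synaptic strength is the area under the activation curve
#' (trapezoidal rule); the half-max width is the total measure of time the
#' curve spends at or above half its maximum, with crossings located by
#' linear interpolation (so multiple volleys contribute the sum of their
#' intervals).
#'
#' @param tc a `dirt_timecourse`, or any list with numeric `times` and
#'   `active` components sampled on an increasing grid.
#' @param bin_width grid spacing used to re-bin a `dirt_timecourse`
#'   (ignored when a plain curve is supplied).
#' @return a `dirt_summary` list with `strength`, `half_max_width`,
#'   `receptor_absorbed`, `astro_absorbed`, and `phi` when known.
#' @export
#' @examples
#' summarize_timecourse(list(times = c(0, 1, 2), active = c(0, 4, 0)))
summarize_timecourse <- function(tc, bin_width = 0.05) {
  if (inherits(tc, "dirt_timecourse")) {
    t_last <- if (length(tc$receptor_recover)) max(tc$receptor_recover) else 0
    times <- seq(0, max(t_last, bin_width), by = bin_width)
    active <- active_receptors(tc, times)
    phi <- tc$config$phi
    extra <- list(receptor_absorbed = tc$receptor_absorbed,
                  astro_absorbed = tc$astro_absorbed)
  } else {
    times <- tc$times
    active <- tc$active
    phi <- tc$phi %||% NA_real_
    extra <- list()
  }
  if (length(times) < 1 || length(times) != length(active)) {
    stopf("time course must supply matching, non-empty times and active vectors")
  }
  strength <- if (length(times) > 1) {
    sum(diff(times) * (utils::head(active, -1) + utils::tail(active, -1)) / 2)
  } else {
    0
  }
  structure(c(list(strength = strength,
                   half_max_width = measure_above_half_max(times, active),
                   phi = phi, n_reps = 1L,
                   strength_sem = NA_real_, width_sem = NA_real_),
              extra),
            class = "dirt_summary")
}

# total measure of {t : curve(t) >= max/2}, linear interpolation between
# samples; 0 for an all-zero curve
measure_above_half_max <- function(times, active) {
  m <- max(active)
  if (m <= 0) {
    return(0)
  }
  h <- m / 2
  above <- active >= h
  n <- length(times)
  if (n == 1) {
    return(0)
  }
  total <- 0
  for (i in seq_len(n - 1)) {
    a1 <- active[i]
    a2 <- active[i + 1]
    dt <- times[i + 1] - times[i]
    if (above[i] && above[i + 1]) {
      total <- total + dt
    } else if (above[i] != above[i + 1] && a1 != a2) {
      frac <- (h - a1) / (a2 - a1) # crossing location within the interval
      total <- total + if (above[i]) frac * dt else (1 - frac) * dt
    }
  }
  total
}

#' Sweep astrocyte protrusion depth and summarize synapse strength/width
#'
#' For each protrusion value, runs `reps` independently seeded simulations
#' and reports the mean and standard error of the synaptic strength and
#' half-max width, plus mean absorption tallies.
#'
#' @param config base [dirt_config()]; its `seed` anchors the sweep's seed
#'   chain.
#' @param phis protrusion depths, each in `[-1, 0.95]`.
#' @param reps number of independent repetitions per depth.
#' @param bin_width grid spacing for the activation curve.
#' @return a tibble with one row per `phi`.
#' @export
protrusion_sweep <- function(config, phis, reps = 20, bin_width = 0.05) {
  stopifnot(inherits(config, "dirt_config"), reps >= 1)
  rows <- lapply(seq_along(phis), function(i) {
    cfgs <- lapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$phi <- phis[i]
      cfg$seed <- derive_seed(config$seed, "dirt_sweep", i, r)
      cfg
    })
    sums <- lapply(cfgs, function(cfg) summarize_timecourse(simulate_dirt(cfg), bin_width))
    strength <- vapply(sums, `[[`, numeric(1), "strength")
    width <- vapply(sums, `[[`, numeric(1), "half_max_width")
    tibble(phi = phis[i],
           strength_mean = mean(strength),
           strength_sem = sd(strength) / sqrt(reps),
           width_mean = mean(width),
           width_sem = sd(width) / sqrt(reps),
           receptor_absorbed_mean = mean(vapply(sums, `[[`, numeric(1), "receptor_absorbed")),
           astro_absorbed_mean = mean(vapply(sums, `[[`, numeric(1), "astro_absorbed")),
           n_reps = reps)
  })
  do.call(rbind, rows)
}

#' Fit a continuous plateau-then-line model
#'
#' Least-squares fit of the piecewise-linear model that is constant below a
#' breakpoint and linear above it,
#' `f(x) = plateau + slope * max(x - breakpoint, 0)`, with the breakpoint
#' found by scanning the input grid and refining between the best
#' neighboring candidates. This is the shape the protrusion sweeps of
#' strength and half-max width follow: flat while the astrocyte sits away
#' from the cleft, then linearly decreasing as it protrudes.
#'
#' @param phis predictor values (at least 4, spanning the breakpoint).
#' @param values response values.
#' @return a `piecewise_linear_fit` with `plateau`, `breakpoint`, `slope`
#'   and `residual` (residual sum of squares).
#' @export
#' @examples
#' x <- seq(-1, 0.95, length.out = 9)
#' y <- 5 + -4 * pmax(x - (-0.2), 0)
#' fit_piecewise_linear(x, y)
fit_piecewise_linear <- function(phis, values) {
  if (length(phis) < 4 || length(values) != length(phis)) {
    stopf("need at least 4 (phi, value) pairs, matched in length")
  }
  ord <- order(phis)
  phis <- phis[ord]
  values <- values[ord]

  rss_at <- function(b) {
    X <- cbind(1, pmax(phis - b, 0))
    fit <- stats::lm.fit(X, values)
    sum(fit$residuals^2)
  }
  # candidates: grid points with at least 2 points strictly above (so the
  # slope is identified); b = min(phis) covers the pure-line degenerate case
  cand <- unique(phis[vapply(phis, function(b) sum(phis > b) >= 2, logical(1))])
  rss <- vapply(cand, rss_at, numeric(1))
  best <- which.min(rss)
  lo <- if (best > 1) cand[best - 1] else cand[best]
  hi <- if (best < length(cand)) cand[best + 1] else cand[best]
  b <- if (hi > lo) optimize(rss_at, c(lo, hi))$minimum else cand[best]
  if (rss_at(cand[best]) < rss_at(b)) b <- cand[best]

  X <- cbind(1, pmax(phis - b, 0))
  fit <- stats::lm.fit(X, values)
  structure(list(plateau = unname(fit$coefficients[1]),
                 breakpoint = b,
                 slope = unname(fit$coefficients[2]),
                 residual = sum(fit$residuals^2)),
            class = "piecewise_linear_fit")
}

#' @export
print.piecewise_linear_fit <- function(x, ...) {
  cat(sprintf("plateau-then-line fit: plateau %.4g, breakpoint %.4g, slope %.4g (RSS %.4g)\n",
              x$plateau, x$breakpoint, x$slope, x$residual))
  invisible(x)
}

#' Evaluate a plateau-then-line fit
#'
#' @param object a `piecewise_linear_fit`.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @return fitted values.
#' @export
predict.piecewise_linear_fit <- function(object, newdata, ...) {
  object$plateau + object$slope * pmax(newdata - object$breakpoint, 0)
}
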