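#' Specify a figure-level experiment protocol
#'
#' Bundles the protocol name, the desk scale, the parameter grid and the
#' master seed for [run_experiment()]. Per-realization and per-cell seeds
#' are deterministic functions of the master seed, so re-running a spec
#' reproduces every artifact exactly; at `scale = 1` the protocols run at
#' the reference network sizes.
#'
#' @param experiment one of `"dirt_sweep"`, `"fig3_synchrony"`,
#'   `"fig4_sweep"`, `"fig5_two_pop"`, `"fig6_spatial"`, `"fig7_ei_sweep"`,
#'   `"s2_dissociation"`.
#' @param scale population-size multiplier in `(0, 1]`; out-degrees scale
#'   proportionally, weights are untouched (see [scale_network_params()]).
#'   `NULL` selects the experiment's desk-scale default: 0.8 for the
#'   one-population synchrony protocols (the smallest scale at which the
#'   default network retains its asynchronous state across every
#'   realization of a 10-network battery; below roughly half the
#'   reference size, finite-size fluctuations entrain collective volleys
#'   even without astrocytes, and up to ~0.7 occasional realizations
#'   still tip through the onset transient), 0.2 for the two-population
#'   correlation protocols, and 0.25 for the spatial protocols.
#' @param n_realizations independent network/drive realizations.
#' @param grid data frame of grid cells (experiment-specific columns,
#'   e.g. `p_e`, `s_en`); `NULL` uses the protocol default.
#' @param master_seed integer master seed.
#' @param t_total trial length (ms).
#' @param reps repetitions per point for `dirt_sweep`.
#' @return an `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("dirt_sweep", "fig3_synchrony",
                                           "fig4_sweep", "fig5_two_pop",
                                           "fig6_spatial", "fig7_ei_sweep",
                                           "s2_dissociation"),
                            scale = NULL, n_realizations = 10, grid = NULL,
                            master_seed = 1, t_total = 5000, reps = 20) {
  experiment <- match.arg(experiment)
  if (is.null(scale)) {
    scale <- switch(experiment,
                    fig3_synchrony = , fig4_sweep = , s2_dissociation = 0.8,
                    fig6_spatial = 0.25, 0.2)
  }
  stopifnot(scale > 0, scale <= 1, n_realizations >= 1)
  structure(list(experiment = experiment, scale = scale,
                 n_realizations = as.integer(n_realizations), grid = grid,
                 master_seed = as.integer(master_seed), t_total = t_total,
                 reps = as.integer(reps)),
            class = "experiment_spec")
}

#' Run a figure-level experiment protocol
#'
#' Executes the protocol at the spec's scale: within one realization the
#' connectivity and feedforward drive are fixed and only the ensheathment
#' (flags and parameters) varies across grid cells, so cell differences
#' are attributable to the astrocytes alone. Unstable (spike-budget
#' truncated) runs are flagged, not dropped.
#'
#' @param spec an [experiment_spec()].
#' @param out_dir optional directory; when given, summary CSVs and a JSON
#'   manifest (seeds, scale, grid) are written there.
#' @return a `sweep_result` list with `summary` (one row per grid cell),
#'   `details` (one row per run) and the spec.
#' @export
run_experiment <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  res <- switch(spec$experiment,
    dirt_sweep = exp_dirt_sweep(spec),
    fig3_synchrony = exp_synchrony_battery(spec),
    fig4_sweep = exp_fig4_sweep(spec),
    fig5_two_pop = exp_two_pop(spec, ei = FALSE),
    fig7_ei_sweep = exp_two_pop(spec, ei = TRUE),
    fig6_spatial = exp_spatial(spec),
    s2_dissociation = exp_dissociation(spec))
  res$spec <- spec
  class(res) <- "sweep_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$summary, file.path(out_dir, paste0(spec$experiment, "_summary.csv")),
                     row.names = FALSE)
    if (!is.null(res$details)) {
      utils::write.csv(res$details, file.path(out_dir, paste0(spec$experiment, "_details.csv")),
                       row.names = FALSE)
    }
    manifest <- list(experiment = spec$experiment, scale = spec$scale,
                     n_realizations = spec$n_realizations,
                     master_seed = spec$master_seed, t_total = spec$t_total,
                     package_version = as.character(utils::packageVersion("astronet")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, paste0(spec$experiment, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("experiment %s (scale %g, %d realization(s)):\n",
              x$spec$experiment, x$spec$scale, x$spec$n_realizations))
  print(x$summary)
  invisible(x)
}

# ---- protocol implementations ---------------------------------------------

exp_dirt_sweep <- function(spec) {
  phis <- spec$grid$phi %||% c(-1, -0.6, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 0.95)
  cfg <- dirt_config(seed = spec$master_seed)
  sweep <- protrusion_sweep(cfg, phis, reps = spec$reps)
  list(summary = sweep,
       fits = list(strength = fit_piecewise_linear(sweep$phi, sweep$strength_mean),
                   width = fit_piecewise_linear(sweep$phi, sweep$width_mean)),
       details = NULL)
}

# one non-spatial run; returns verdict, rates, stability
run_nonspatial_cell <- function(conn, params, ens, drive, t_total, seed_noise,
                                seed_init, burn_in = 500) {
  cfg <- sim_config(t_total = t_total, burn_in = burn_in,
                    seed_noise = seed_noise, seed_init = seed_init)
  sim <- simulate_network(conn, params, ens, drive, cfg)
  raster <- sim$raster
  t0 <- min(burn_in, raster$t_end / 2)
  verdict <- classify_synchrony(raster, t_range = c(t0, raster$t_end))
  rates <- firing_rates(raster, t_range = c(t0, raster$t_end))
  list(raster = raster,
       synchronous = verdict$synchronous || raster$truncated,
       sync_index = verdict$sync_index,
       e_rate = unname(rates$per_pop["e"]),
       unstable = raster$truncated)
}

exp_synchrony_battery <- function(spec) {
  params <- scale_network_params(network_params("nonspatial"), spec$scale)
  grid <- spec$grid %||% data.frame(p_e = c(0, 0.7), s_en = c(0, 0.5))
  ms <- spec$master_seed
  rows <- list()
  for (r in seq_len(spec$n_realizations)) {
    conn <- build_nonspatial(params, derive_seed(ms, "conn", r))
    for (ci in seq_len(nrow(grid))) {
      ens <- ensheathment_params(s_en = grid$s_en[ci], p_e = grid$p_e[ci],
                                 seed = derive_seed(ms, "ens", r, ci))
      out <- run_nonspatial_cell(conn, params, ens, shared_noise_drive(),
                                 spec$t_total, derive_seed(ms, "noise", r),
                                 derive_seed(ms, "init", r))
      rows[[length(rows) + 1]] <- tibble(
        cell = ci, p_e = grid$p_e[ci], s_en = grid$s_en[ci], realization = r,
        synchronous = out$synchronous, sync_index = out$sync_index,
        e_rate = out$e_rate, unstable = out$unstable)
    }
  }
  details <- do.call(rbind, rows)
  summary <- aggregate_cells(details, c("cell", "p_e", "s_en"))
  list(summary = summary, details = details)
}

exp_fig4_sweep <- function(spec) {
  if (is.null(spec$grid)) {
    spec$grid <- expand.grid(p_e = seq(0.1, 1, by = 0.1),
                             s_en = seq(0.2, 0.8, by = 0.1))
  }
  exp_synchrony_battery(spec)
}

exp_dissociation <- function(spec) {
  params <- scale_network_params(network_params("nonspatial"), spec$scale)
  grid <- spec$grid %||% data.frame(p_e = 0.7, s_en = 0.4)
  ms <- spec$master_seed
  rows <- list()
  for (r in seq_len(spec$n_realizations)) {
    conn <- build_nonspatial(params, derive_seed(ms, "conn", r))
    for (mode in c("both", "j_only", "tau_only")) {
      # one flag seed per realization: the flagged synapse set is shared
      # across modes, so the comparison is controlled
      ens <- ensheathment_params(s_en = grid$s_en[1], p_e = grid$p_e[1],
                                 mode = mode, seed = derive_seed(ms, "ens", r))
      out <- run_nonspatial_cell(conn, params, ens, shared_noise_drive(),
                                 spec$t_total, derive_seed(ms, "noise", r),
                                 derive_seed(ms, "init", r))
      rows[[length(rows) + 1]] <- tibble(
        mode = mode, realization = r, p_e = grid$p_e[1], s_en = grid$s_en[1],
        synchronous = out$synchronous, sync_index = out$sync_index,
        e_rate = out$e_rate, unstable = out$unstable)
    }
  }
  details <- do.call(rbind, rows)
  summary <- aggregate_cells(details, "mode")
  list(summary = summary, details = details)
}

exp_two_pop <- function(spec, ei = FALSE) {
  params <- scale_network_params(network_params("nonspatial"), spec$scale)
  grid <- spec$grid %||% if (ei) {
    expand.grid(p_e = c(0.2, 0.5, 0.8), p_i = c(0, 0.4, 0.8), s_en = 0.5)
  } else {
    expand.grid(p_e = c(0.2, 0.5, 0.8), p_i = 0, s_en = c(0.2, 0.35, 0.5))
  }
  if (is.null(grid$p_i)) grid$p_i <- 0
  ms <- spec$master_seed
  rows <- list()
  for (r in seq_len(spec$n_realizations)) {
    conn <- build_nonspatial(params, derive_seed(ms, "conn", r))
    drive <- two_population_drive(seed_split = derive_seed(ms, "split", r))
    cfg <- sim_config(t_total = spec$t_total,
                      seed_noise = derive_seed(ms, "noise", r),
                      seed_init = derive_seed(ms, "init", r))
    for (ci in seq_len(nrow(grid))) {
      ens <- ensheathment_params(s_en = grid$s_en[ci], p_e = grid$p_e[ci],
                                 p_i = grid$p_i[ci],
                                 seed = derive_seed(ms, "ens", r, ci))
      sim <- simulate_network(conn, params, ens, drive, cfg)
      raster <- sim$raster
      t0 <- min(cfg$burn_in, raster$t_end / 2)
      tr <- c(t0, raster$t_end)
      cs <- spike_count_correlations(raster, sample = NULL, n_sample = 1000,
                                     seed = derive_seed(ms, "corrsample", r),
                                     t_range = tr, groups = raster$group)
      rates <- firing_rates(raster, t_range = tr)
      rows[[length(rows) + 1]] <- tibble(
        cell = ci, p_e = grid$p_e[ci], p_i = grid$p_i[ci], s_en = grid$s_en[ci],
        realization = r,
        mean_within_corr = cs$by_group$within %||% NA_real_,
        mean_across_corr = cs$by_group$across %||% NA_real_,
        mean_corr = cs$mean_corr,
        mean_e_rate = unname(rates$per_pop["e"]),
        unstable = raster$truncated)
    }
  }
  details <- do.call(rbind, rows)
  agg <- function(v, f) tapply(v, f, mean, na.rm = TRUE)
  key <- interaction(details$cell, drop = TRUE)
  summary <- tibble(
    cell = as.integer(as.character(tapply(details$cell, key, `[`, 1))),
    p_e = as.numeric(tapply(details$p_e, key, `[`, 1)),
    p_i = as.numeric(tapply(details$p_i, key, `[`, 1)),
    s_en = as.numeric(tapply(details$s_en, key, `[`, 1)),
    mean_within_corr = as.numeric(agg(details$mean_within_corr, key)),
    mean_across_corr = as.numeric(agg(details$mean_across_corr, key)),
    mean_e_rate = as.numeric(agg(details$mean_e_rate, key)),
    fraction_unstable = as.numeric(agg(as.numeric(details$unstable), key)))
  summary <- summary[order(summary$cell), ]
  list(summary = summary, details = details)
}

exp_spatial <- function(spec) {
  grid <- spec$grid %||% data.frame(alpha_rec = c(0.05, 0.05, 0.2, 0.2),
                                    p_e = c(0, 0.9, 0, 0.8),
                                    s_en = c(0, 0.5, 0, 0.5))
  ms <- spec$master_seed
  rows <- list()
  curves <- list()
  base <- scale_network_params(network_params("spatial"), spec$scale)
  for (r in seq_len(spec$n_realizations)) {
    for (ci in seq_len(nrow(grid))) {
      params <- base
      params$alpha_rec <- grid$alpha_rec[ci]
      conn <- build_spatial(params, derive_seed(ms, "conn", r, grid$alpha_rec[ci] * 100))
      ens <- ensheathment_params(s_en = grid$s_en[ci], p_e = grid$p_e[ci],
                                 seed = derive_seed(ms, "ens", r, ci))
      cfg <- sim_config(t_total = spec$t_total,
                        seed_noise = derive_seed(ms, "noise", r),
                        seed_init = derive_seed(ms, "init", r))
      sim <- simulate_network(conn, params, ens, poisson_drive(), cfg)
      raster <- sim$raster
      t0 <- min(cfg$burn_in, raster$t_end / 2)
      cvd <- correlation_vs_distance(raster, window = 250, n_sample = 1000,
                                     seed = derive_seed(ms, "corrsample", r),
                                     t_range = c(t0, raster$t_end))
      rates <- firing_rates(raster, t_range = c(t0, raster$t_end))
      curves[[length(curves) + 1]] <- cbind(cell = ci, realization = r, cvd)
      rows[[length(rows) + 1]] <- tibble(
        cell = ci, alpha_rec = grid$alpha_rec[ci], p_e = grid$p_e[ci],
        s_en = grid$s_en[ci], realization = r,
        mean_corr = mean(cvd$mean_corr, na.rm = TRUE),
        max_abs_corr = max(abs(cvd$mean_corr), na.rm = TRUE),
        mean_e_rate = unname(rates$per_pop["e"]),
        unstable = raster$truncated)
    }
  }
  list(summary = do.call(rbind, rows), details = do.call(rbind, curves))
}

aggregate_cells <- function(details, keys) {
  key <- interaction(details[keys], drop = TRUE)
  out <- details[!duplicated(key), keys, drop = FALSE]
  ord <- order(key[!duplicated(key)])
  out <- out[ord, , drop = FALSE]
  out$fraction_synchronous <- as.numeric(tapply(as.numeric(details$synchronous), key, mean))
  out$mean_e_rate <- as.numeric(tapply(details$e_rate, key, mean))
  out$fraction_unstable <- as.numeric(tapply(as.numeric(details$unstable), key, mean))
  out$n_realizations <- as.integer(tapply(details$synchronous, key, length))
  as_tibble(out)
}

#' Inspect a sweep along a naive-mean-field isoline
#'
#' Selects the grid cells whose `p_e * s_en` equals `s_hat` within `tol`
#' and orders them by `p_e`, for inspecting whether the synchrony fraction
#' is constant along the isoline (it is not, which is the failure of the
#' naive mean field).
#'
#' @param s_hat target product `p_e * s_en`.
#' @param result a `sweep_result` from a synchrony sweep.
#' @param tol isoline tolerance.
#' @return tibble of isoline cells ordered by `p_e` (empty, with a
#'   warning, if no cell lies on the isoline).
#' @export
isoline_comparison <- function(s_hat, result, tol = 0.02) {
  s <- result$summary
  stopifnot(!is.null(s$p_e), !is.null(s$s_en))
  on_iso <- abs(s$p_e * s$s_en - s_hat) <= tol
  if (!any(on_iso)) {
    warning(sprintf("no grid cells on the p_e * s_en = %g isoline (tol %g)", s_hat, tol))
  }
  out <- s[on_iso, , drop = FALSE]
  out[order(out$p_e), , drop = FALSE]
}

#' Generate deterministic synthetic fixtures
#'
#' Small constructed inputs exercising the analysis operations without
#' running the simulator: independent Poisson rasters, volley-structured
#' synchronous rasters, two-group rasters with anti-correlated rate
#' envelopes, and noisy plateau-then-line curves.
#'
#' @param kind `"poisson_raster"`, `"synchronous_raster"`,
#'   `"two_group_raster"`, or `"piecewise_curve"`.
#' @param params named list of kind-specific parameters (see the defaults
#'   in the implementation).
#' @param seed integer seed.
#' @param dir optional directory; when given, the fixture is also written
#'   as a plain-text table and the path returned as an attribute.
#' @return a [spike_raster()] or a tibble (`piecewise_curve`).
#' @export
generate_fixture <- function(kind = c("poisson_raster", "synchronous_raster",
                                      "two_group_raster", "piecewise_curve"),
                             params = list(), seed = 1, dir = NULL) {
  kind <- match.arg(kind)
  p <- utils::modifyList(switch(kind,
    poisson_raster = list(n = 200, rate = 5, t_total = 5000),
    synchronous_raster = list(n = 200, period = 100, jitter = 2,
                              participation = 0.9, t_total = 5000),
    two_group_raster = list(n = 200, rate = 10, mod = 0.8, period = 500,
                            t_total = 5000),
    piecewise_curve = list(plateau = 5, breakpoint = -0.2, slope = -4,
                           noise_sd = 0,
                           phis = c(-1, -0.6, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 0.95))),
    params)
  out <- switch(kind,
    poisson_raster = {
      r <- generate_poisson_ffwd(p$n, p$rate, p$t_total, seed)
      r$pop <- rep("e", p$n)
      r
    },
    synchronous_raster = with_seed(seed, {
      volleys <- seq(p$period, p$t_total - p$period / 2, by = p$period)
      ev <- do.call(rbind, lapply(volleys, function(v) {
        who <- which(runif(p$n) < p$participation)
        cbind(who, pmax(0, v + rnorm(length(who), 0, p$jitter)))
      }))
      spike_raster(ev[, 1], ev[, 2], p$n, pop = rep("e", p$n),
                   t_end = p$t_total)
    }),
    two_group_raster = with_seed(seed, {
      # doubly stochastic: group envelopes modulate in antiphase
      rate_max <- p$rate * (1 + p$mod)
      counts <- rpois(p$n, rate_max * p$t_total / 1000)
      neuron <- rep(seq_len(p$n), counts)
      time <- runif(sum(counts), 0, p$t_total)
      grp <- rep(c(1L, 2L), length.out = p$n)
      sgn <- ifelse(grp[neuron] == 1L, 1, -1)
      lambda <- p$rate * (1 + sgn * p$mod * sin(2 * pi * time / p$period))
      keep <- runif(length(time)) < lambda / rate_max
      r <- spike_raster(neuron[keep], time[keep], p$n, pop = rep("e", p$n),
                        group = grp, t_end = p$t_total)
      r$events <- r$events[order(r$events$time), ]
      r
    }),
    piecewise_curve = with_seed(seed, {
      tibble(phi = p$phis,
             value = p$plateau + p$slope * pmax(p$phis - p$breakpoint, 0) +
               rnorm(length(p$phis), 0, p$noise_sd))
    }))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, paste0(kind, ".csv"))
    if (kind == "piecewise_curve") {
      utils::write.csv(out, path, row.names = FALSE)
    } else {
      utils::write.csv(out$events, path, row.names = FALSE)
    }
    attr(out, "path") <- path
  }
  out
}
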