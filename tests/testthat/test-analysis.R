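test_that("spike-count correlations hit the closed-form extremes", {
  tt <- seq(50, 4950, by = 100)
  # two identical trains -> 1
  r <- spike_raster(c(rep(1, length(tt)), rep(2, length(tt))), c(tt, tt), 3,
                    t_end = 5000)
  cs <- spike_count_correlations(r, window = 250, sample = 1:2)
  expect_equal(cs$mean_corr, 1)
  # strictly alternating windows -> -1
  w <- 250
  t1 <- seq(0, 4750, by = 500) + 100   # even windows
  t2 <- seq(250, 4750, by = 500) + 100 # odd windows
  r2 <- spike_raster(c(rep(1, length(t1)), rep(2, length(t2))), c(t1, t2), 2,
                     t_end = 5000)
  cs2 <- spike_count_correlations(r2, window = w, sample = 1:2)
  expect_equal(cs2$mean_corr, -1)
})

test_that("independent Poisson trains decorrelate", {
  r <- generate_poisson_ffwd(40, 10, 2e5, seed = 3)
  r$pop <- rep("e", 40)
  cs <- spike_count_correlations(r, window = 250, sample = 1:40)
  n_win <- floor(2e5 / 250)
  expect_lt(abs(cs$mean_corr), 3 / sqrt(n_win))
  expect_equal(cs$n_pairs, choose(40, 2))
})

test_that("zero-variance neurons are excluded, not imputed", {
  tt <- seq(50, 950, by = 50)
  r <- spike_raster(rep(1, length(tt)), tt, 3, t_end = 1000)
  cs <- spike_count_correlations(r, window = 100, sample = 1:3)
  expect_equal(cs$n_excluded, 2L)
  expect_equal(cs$n_pairs, 0L)
})

test_that("correlations are invariant to id relabeling and time shifts", {
  r <- generate_poisson_ffwd(12, 20, 5e4, seed = 9)
  r$pop <- rep("e", 12)
  base <- spike_count_correlations(r, window = 250, sample = 1:12)
  shifted <- r
  shifted$events$time <- shifted$events$time + 777
  shifted$t_end <- r$t_end + 777
  cs_shift <- spike_count_correlations(shifted, window = 250, sample = 1:12,
                                       t_range = c(777, 777 + 5e4))
  expect_equal(cs_shift$mean_corr, base$mean_corr)
  relab <- r
  relab$events$neuron <- 13L - relab$events$neuron
  cs_rel <- spike_count_correlations(relab, window = 250, sample = 1:12)
  expect_equal(cs_rel$mean_corr, base$mean_corr)
})

test_that("within/across means reconstruct the global mean by pair counts", {
  r <- generate_fixture("two_group_raster", seed = 5)
  cs <- spike_count_correlations(r, window = 250, sample = seq_len(r$n_neurons),
                                 groups = r$group)
  bg <- cs$by_group
  recon <- (bg$within * bg$n_within + bg$across * bg$n_across) /
    (bg$n_within + bg$n_across)
  expect_equal(recon, cs$mean_corr)
  # anti-correlated group envelopes: within positive, across negative
  expect_gt(bg$within, 0)
  expect_lt(bg$across, 0)
  expect_gt(bg$within, bg$across)
})

test_that("distance-resolved correlations recover degenerate cases", {
  n <- 30
  tt <- seq(100, 9900, by = 200)
  pos <- astronet:::grid_positions(5)[rep(1:25, length.out = n), ]
  # every neuron carries one shared train -> every bin at 1
  r <- spike_raster(rep(1:n, each = length(tt)), rep(tt, n), n,
                    pop = rep("e", n), positions = pos, t_end = 1e4)
  cvd <- correlation_vs_distance(r, window = 250, sample = 1:n)
  expect_true(all(abs(cvd$mean_corr[cvd$n_pairs > 0] - 1) < 1e-12))
  # independent Poisson -> near zero everywhere
  rp <- generate_poisson_ffwd(n, 10, 1e5, seed = 4)
  rp$pop <- rep("e", n)
  rp$positions <- pos
  cvd0 <- correlation_vs_distance(rp, window = 250, sample = 1:n)
  expect_true(all(abs(cvd0$mean_corr[cvd0$n_pairs > 0]) < 0.1))
})

test_that("synchrony classification separates volleys from Poisson firing", {
  sync <- generate_fixture("synchronous_raster", seed = 2)
  v1 <- classify_synchrony(sync)
  expect_true(v1$synchronous)
  pois <- generate_fixture("poisson_raster", list(n = 1000, rate = 5), seed = 3)
  v2 <- classify_synchrony(pois)
  expect_false(v2$synchronous)
  expect_lt(v2$sync_index, 5)
  empty <- spike_raster(integer(0), numeric(0), 10, t_end = 1000)
  v3 <- classify_synchrony(empty)
  expect_false(v3$synchronous)
  expect_equal(v3$sync_index, 0)
})

test_that("compressing spikes into volleys never lowers the synchrony verdict", {
  pois <- generate_fixture("poisson_raster", list(n = 300, rate = 8), seed = 7)
  v0 <- classify_synchrony(pois)
  squeezed <- pois
  squeezed$events$time <- (floor(pois$events$time / 100) + 0.5) * 100
  v1 <- classify_synchrony(squeezed)
  expect_gt(v1$sync_index, v0$sync_index)
  expect_true(v1$synchronous)
})

test_that("rheobase matches a numeric maximization of the subthreshold balance", {
  p <- network_params()
  for (pop in c("e", "i")) {
    v <- seq(-80, -10, by = 1e-3)
    drift <- (v - p$e_l) / p$tau_m[pop] -
      (p$delta_t[pop] / p$tau_m[pop]) * exp((v - p$v_t) / p$delta_t[pop])
    expect_equal(rheobase(p, pop), max(drift), tolerance = 1e-6)
  }
  expect_equal(rheobase(p, "e"), 8 / 15)
  expect_equal(rheobase(p, "i"), 0.95)
  # Delta_T -> 0 limit: LIF rheobase (V_T - E_L)/tau_m
  p2 <- network_params(delta_t = c(e = 1e-9, i = 1e-9))
  expect_equal(rheobase(p2, "e"), (p$v_t - p$e_l) / 15, tolerance = 1e-8)
})

test_that("firing rates count spikes over the analysis window", {
  empty <- spike_raster(integer(0), numeric(0), 5, pop = rep("e", 5), t_end = 1000)
  expect_true(all(firing_rates(empty)$per_neuron$rate_hz == 0))
  r <- spike_raster(rep(1, 50), seq(100, 9999, length.out = 50), 1,
                    pop = "e", t_end = 10000)
  expect_equal(firing_rates(r)$per_neuron$rate_hz, 5)
  reg <- spike_raster(rep(1, 50), seq(50, 4950, by = 100), 1, pop = "e",
                      t_end = 5000)
  expect_equal(firing_rates(reg)$per_neuron$rate_hz, 10)
})

mock_currents <- function(time, ffwd, rec_e, rec_i, dt) {
  structure(list(time = time, ffwd = cbind(ffwd), rec_e = cbind(rec_e),
                 rec_i = cbind(rec_i), ids = 1L, pop = "e", dt_sample = dt),
            class = "current_record")
}

test_that("shared-current decomposition normalizes, centers, and filters", {
  dt <- 0.5
  tt <- seq(0, 4000 - dt, by = dt)
  # constant input -> identically zero trace
  cc <- mock_currents(tt, rep(2, length(tt)), rep(0.5, length(tt)),
                      rep(-1, length(tt)), dt)
  sf <- shared_current_decomposition(cc, network_params())
  expect_true(all(abs(sf$traces$ffwd) < 1e-12))
  expect_true(all(abs(sf$traces$total) < 1e-12))
  # slow sinusoid: amplitude scaled by 1/rheobase, Gaussian attenuation
  per <- 1000
  amp <- 0.2
  sine <- amp * sin(2 * pi * tt / per)
  cc2 <- mock_currents(tt, 2 + sine, rep(0, length(tt)), rep(0, length(tt)), dt)
  sf2 <- shared_current_decomposition(cc2, network_params(), kernel_sigma = 15)
  atten <- exp(-(2 * pi / per)^2 * 15^2 / 2)
  expected_amp <- amp * atten / rheobase(network_params(), "e")
  mid <- sf2$traces$ffwd[tt > 500 & tt < 3500]
  expect_equal(max(mid), expected_amp, tolerance = 0.02)
  # every trace is zero-mean
  expect_lt(abs(mean(sf2$traces$ffwd)), 1e-10)
})

test_that("shared-current decomposition is linear in its inputs", {
  dt <- 0.5
  tt <- seq(0, 1000 - dt, by = dt)
  set.seed(31)
  a <- rnorm(length(tt))
  b <- rnorm(length(tt))
  z <- rep(0, length(tt))
  f <- function(x) shared_current_decomposition(
    mock_currents(tt, x, z, z, dt), network_params())$traces$ffwd
  expect_equal(f(a + 2 * b), f(a) + 2 * f(b), tolerance = 1e-10)
})
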