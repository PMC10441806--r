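test_that("default parameter sets reproduce the reference tables", {
  p <- network_params()
  expect_equal(unname(p$tau_m), c(15, 10))
  expect_equal(c(p$v_th, p$v_t, p$e_l, p$v_re), c(-10, -50, -60, -65))
  expect_equal(unname(p$tau_ref), c(1.5, 0.5))
  expect_equal(unname(p$tau_syn), c(5, 4))
  expect_equal(unname(p$delta_t), c(2, 0.5))
  expect_equal(c(p$tau_s, unname(p$m), p$sigma_s), c(40, 0.015, 0.01, 0.1))
  expect_true(all(p$k_out == 2500))
  expect_equal(as.vector(p$j), c(12.5, 20, -50, -50))
  s <- network_params("spatial")
  expect_equal(c(s$n_e, s$n_i, s$n_f), c(40000, 10000, 5625))
  expect_equal(as.vector(s$k_out), c(2000, 500, 2000, 500))
  expect_equal(as.vector(s$j), c(40, 120, -400, -400))
  expect_equal(unname(s$tau_syn), c(6, 5))
  expect_equal(s$r_f, 5)
})

test_that("sign and out-degree invariants are enforced", {
  expect_error(network_params(j = matrix(c(-1, 20, -50, -50), 2, 2)),
               "excitatory weights")
  expect_error(network_params(n_e = 100L, n_i = 100L), "out-degree")
})

test_that("non-spatial builder fixes the out-degree exactly", {
  net <- tiny_net()
  conn <- net$conn
  k <- net$params$k_out
  et <- edge_table(conn)
  outdeg <- table(et$pre, et$post_pop)
  expect_true(all(outdeg[, "e"] == k["e", "e"]))
  expect_true(all(outdeg[, "i"] == k["i", "e"]))
  # no self-connections, no duplicate edges per (pre, target)
  expect_false(any(et$pre == et$post))
  expect_false(any(duplicated(et[, c("pre", "post")])))
})

test_that("zero out-degree gives an empty edge list and too-large is rejected", {
  k0 <- matrix(0L, 2, 2, dimnames = list(c("e", "i"), c("e", "i")))
  p <- network_params(n_e = 20L, n_i = 20L, k_out = k0)
  conn <- build_nonspatial(p, seed = 1)
  expect_equal(length(conn$post), 0L)
  p2 <- network_params(n_e = 20L, n_i = 20L,
                       k_out = matrix(20L, 2, 2, dimnames = list(c("e", "i"), c("e", "i"))))
  expect_error(build_nonspatial(p2, seed = 1), "self excluded")
})

test_that("in-degrees fluctuate around the conserved out-degree", {
  # edge conservation fixes the mean in-degree per source population at
  # exactly k_out, while individual in-degrees are random
  k <- matrix(5L, 2, 2, dimnames = list(c("e", "i"), c("e", "i")))
  p <- network_params(n_e = 40L, n_i = 40L, k_out = k)
  indeg_sd <- vapply(1:25, function(s) {
    et <- edge_table(build_nonspatial(p, seed = s))
    ee <- et[et$pre_pop == "e" & et$post_pop == "e", ]
    indeg <- tabulate(ee$post, nbins = 40)
    expect_equal(mean(indeg), 5) # exact conservation
    sd(indeg)
  }, numeric(1))
  expect_gt(mean(indeg_sd), 0)
  # binomial-like spread: sd ~ sqrt(k * (1 - k/n)) across the census
  expect_lt(abs(mean(indeg_sd) - sqrt(5 * 35 / 40)) / sqrt(5 * 35 / 40), 0.25)
})

test_that("graph generation is a pure function of (params, seed)", {
  p <- network_params(n_e = 50L, n_i = 50L,
                      k_out = matrix(10L, 2, 2, dimnames = list(c("e", "i"), c("e", "i"))))
  c1 <- build_nonspatial(p, seed = 7)
  c2 <- build_nonspatial(p, seed = 7)
  c3 <- build_nonspatial(p, seed = 8)
  expect_identical(c1$post, c2$post)
  expect_false(identical(c1$post, c3$post))
})

test_that("wrapped Gaussian is a symmetric unit-mass periodic density", {
  for (alpha in c(0.05, 0.1, 0.2)) {
    u <- seq(0, 1, length.out = 2001)
    g <- wrapped_gaussian(u, alpha)
    mass <- sum((g[-1] + g[-length(g)]) / 2) * diff(u)[1]
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  u <- seq(0.01, 0.99, by = 0.07)
  expect_equal(wrapped_gaussian(u, 0.1), wrapped_gaussian(1 - u, 0.1))
  # wide limit: flat density
  expect_lt(max(abs(wrapped_gaussian(seq(0, 1, 0.01), 10) - 1)), 1e-6)
  expect_error(wrapped_gaussian(0.5, 0), "alpha")
})

test_that("torus distance wraps, is symmetric, and is bounded by sqrt(2)/2", {
  expect_equal(torus_distance(c(0, 0), c(0.9, 0)), 0.1)
  expect_equal(torus_distance(c(0.2, 0.3), c(0.2, 0.3)), 0)
  expect_equal(torus_distance(c(0.1, 0.9), c(0.8, 0.2)),
               torus_distance(c(0.8, 0.2), c(0.1, 0.9)))
  set.seed(1)
  x <- matrix(runif(200), ncol = 2)
  y <- matrix(runif(200), ncol = 2)
  expect_lte(max(torus_distance(x, y)), sqrt(2) / 2)
  expect_equal(torus_distance(c(0, 0), c(0.5, 0.5)), sqrt(2) / 2)
})

test_that("spatial builder fixes out-degree and places neurons on grids", {
  p <- scale_network_params(network_params("spatial"), 0.04)
  conn <- build_spatial(p, seed = 3)
  expect_equal(length(conn$post), (p$k_out["e", "e"] + p$k_out["i", "e"]) * p$n_e +
                 (p$k_out["e", "i"] + p$k_out["i", "i"]) * p$n_i)
  expect_true(all(diff(conn$pre_ptr)[seq_len(p$n_e)] ==
                    p$k_out["e", "e"] + p$k_out["i", "e"]))
  expect_equal(nrow(conn$positions), p$n_e + p$n_i)
  expect_equal(length(conn$ffwd_post), sum(p$k_out_ffwd) * p$n_f)
  expect_error(build_spatial(network_params("spatial", n_e = 40001L), seed = 1),
               "perfect squares")
})

test_that("spatial contact counts follow the wrapped-Gaussian profile", {
  # one presynaptic neuron at the torus center; empirical per-site contact
  # counts across seeds vs the expected profile (k/N) g(dx) g(dy)
  side <- 15
  k <- 100
  alpha <- 0.15
  n_rep <- 150
  counts <- numeric(side^2)
  pre <- matrix(c(0.5, 0.5), 1)
  for (r in seq_len(n_rep)) {
    tid <- astronet:::with_seed(1000 + r,
      astronet:::sample_contacts(pre, k, alpha, side))
    tab <- tabulate(tid, nbins = side^2)
    counts <- counts + tab
  }
  emp <- counts / n_rep
  pos <- astronet:::grid_positions(side)
  # exact expectation of the displacement-and-snap scheme: the wrapped
  # Gaussian mass of each grid cell, per axis
  cellmass <- function(u, a) {
    h <- 1 / (2 * side)
    ks <- -3:3
    rowSums(outer(u, ks, function(x, b) pnorm(x + b + h, 0, a) - pnorm(x + b - h, 0, a)))
  }
  expected <- k * cellmass(pos[, 1] - 0.5, alpha) * cellmass(pos[, 2] - 0.5, alpha)
  # aggregate by distance bins to tame per-site noise
  d <- torus_distance(pos, matrix(c(0.5, 0.5), 1))
  bin <- cut(d, seq(0, 0.75, 0.1), include.lowest = TRUE)
  emp_b <- tapply(emp, bin, mean)
  exp_b <- tapply(expected, bin, mean)
  # per-site counts are Poisson-like, so the bin mean's sampling error is
  # sqrt(mean expected count / (repetitions x sites in bin))
  n_sites <- tapply(expected, bin, length)
  sem_b <- sqrt(exp_b / (n_rep * n_sites))
  ok <- !is.na(emp_b)
  expect_true(all(abs(emp_b[ok] - exp_b[ok]) <= 3 * sem_b[ok] + 0.005 * max(exp_b[ok])))
  # ... and the continuum profile (k/N) g(dx) g(dy) matches the cell law
  # up to the discretization bias of evaluating the density mid-cell
  profile <- k / side^2 *
    wrapped_gaussian(pos[, 1] - 0.5, alpha) * wrapped_gaussian(pos[, 2] - 0.5, alpha)
  expect_lt(max(abs(profile - expected)) / max(expected), 0.05)
  # total contacts are conserved exactly
  expect_equal(sum(counts), n_rep * k)
})

test_that("translating the grids leaves the edge set invariant on the torus", {
  # shifting every grid by the same torus offset relocates neurons and
  # displacement targets together: in index space the edge list is
  # unchanged while all positions move by the shift
  p <- scale_network_params(network_params("spatial"), 0.01)
  side_e <- sqrt(p$n_e)
  shift <- c(3 / side_e, 3 / side_e)
  c0 <- build_spatial(p, seed = 5)
  c1 <- build_spatial(p, seed = 5, origin = shift)
  expect_identical(c0$post, c1$post)
  expect_identical(c0$ffwd_post, c1$ffwd_post)
  d <- (c1$positions - c0$positions) %% 1
  expect_true(all(abs(d - shift[1]) < 1e-12 | abs(d - shift[1] - 1) < 1e-12 |
                    abs(d - shift[1] + 1) < 1e-12))
})
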