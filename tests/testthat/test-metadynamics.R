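test_that("bias energy matches the naive summation oracle", {
  set.seed(5)
  h <- gen_hills(100, widths = c(x = 0.1, y = 0.2), seed = 5)
  pts <- cbind(runif(50, -1, 1), runif(50, -1, 1))
  expect_equal(bias_energy(h, pts), bias_oracle(h, pts), tolerance = 1e-10)
  # time truncation agrees too
  tcut <- h$time[40]
  expect_equal(bias_energy(h, pts, upto_time = tcut),
               bias_oracle(h, pts, upto_time = tcut), tolerance = 1e-10)
})

test_that("bias of an empty history is zero and a single hill peaks at its height", {
  h0 <- new_hills(tibble::tibble(time = numeric(0), x = numeric(0),
                                 sigma_x = numeric(0), height = numeric(0)), "x")
  expect_equal(bias_energy(h0, c(0.3, -0.5)), c(0, 0))
  h1 <- new_hills(tibble::tibble(time = 0.1, x = 0.4, sigma_x = 0.1,
                                 height = 1.3), "x")
  expect_equal(bias_energy(h1, 0.4), 1.3)
  expect_lt(bias_energy(h1, 0.9), 1.3)
})

test_that("bias energy is non-decreasing in upto_time", {
  h <- gen_hills(60, widths = c(x = 0.1), seed = 9)
  pts <- seq(-1, 1, length.out = 11)
  cuts <- sort(sample(h$time, 6))
  prev <- rep(0, length(pts))
  for (ct in cuts) {
    cur <- bias_energy(h, pts, upto_time = ct)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("dimension mismatches and invalid hills are rejected", {
  h <- gen_hills(5, widths = c(x = 0.1, y = 0.1), seed = 1)
  expect_error(bias_energy(h, matrix(0, 2, 3)), "dimension")
  expect_error(new_hills(tibble::tibble(time = c(1, 2), x = c(0, 0),
                                        sigma_x = c(0.1, 0.1),
                                        height = c(1, -1)), "x"),
               "positive")
  expect_error(new_hills(tibble::tibble(time = c(2, 1), x = c(0, 0),
                                        sigma_x = c(0.1, 0.1),
                                        height = c(1, 1)), "x"),
               "increasing")
})

test_that("single-hill landscape is an inverted Gaussian of the hill height", {
  h1 <- new_hills(tibble::tibble(time = 0.1, x = 0.2, sigma_x = 0.15,
                                 height = 0.8), "x")
  grid <- seq(-1, 1, length.out = 201)
  fel <- reconstruct_fel(h1, list(x = grid))
  expect_equal(min(fel$fel), 0)
  expect_equal(fel$x[which.min(fel$fel)], 0.2, tolerance = 0.01)
  # depth equals the hill height up to the far-tail shift
  expect_equal(max(fel$fel) - min(fel$fel), 0.8, tolerance = 1e-6)
  # shape: fel - max equals the negated Gaussian
  expect_equal(fel$fel, 0.8 - 0.8 * exp(-(grid - 0.2)^2 / (2 * 0.15^2)),
               tolerance = 1e-9)
})

test_that("landscape of a symmetric hill pair is symmetric about the midpoint", {
  h <- new_hills(tibble::tibble(time = c(0.1, 0.2), x = c(-0.3, 0.3),
                                sigma_x = 0.1, height = 0.5), "x")
  grid <- seq(-1, 1, length.out = 201)  # symmetric about 0
  fel <- reconstruct_fel(h, list(x = grid))
  expect_equal(fel$fel, rev(fel$fel), tolerance = 1e-10)
  expect_equal(min(fel$fel), 0)
})

test_that("hill bookkeeping converts counts to picoseconds with half-up rounding", {
  res <- hill_count_to_time(c(909, 885), stride = 250, timestep = 0.5)
  expect_equal(res$time_ps_rounded, c(113.63, 110.63))
  expect_equal(res$time_ps, c(113.625, 110.625))
  res2 <- hill_count_to_time(c(897, 1644), stride = 100, timestep = 0.5)
  expect_equal(res2$time_ps_rounded, c(44.85, 82.2))
  expect_equal(hill_count_to_time(1, 1, 1)$time_ps, 0.001)
  expect_error(hill_count_to_time(0, 250, 0.5), "positive")
})

test_that("height schedule switches exactly after the configured hill count", {
  h <- gen_hills(909, stride = 250, timestep = 0.5, initial_height = 1.0,
                 reduced_height = 0.5, switch_after = 599, seed = 2)
  expect_equal(h$height[599], 1.0)
  expect_equal(h$height[600], 0.5)
  expect_true(all(h$height[1:599] == 1.0))
  expect_true(all(h$height[600:909] == 0.5))
  expect_equal(max(h$time), 113.625)
  expect_equal(h$time, h$index * 250 * 0.5 / 1000, tolerance = 1e-9)
})

test_that("zero-temperature unbiased dynamics stays at a fixed point", {
  pot <- toy_potential("double_well", barrier = 5, temperature = 1e-12)
  run <- run_toy_metadynamics(pot, x0 = -1, n_hills = 4, stride = 50,
                              width = 0.1, initial_height = 1e-12,
                              reduced_height = 1e-12, switch_after = 1,
                              seed = 1, record_every = 5)
  expect_true(all(abs(run$colvar$x + 1) < 1e-6))
})

test_that("unbiased harmonic sampling satisfies equipartition", {
  pot <- toy_potential("harmonic", k = 10)
  run <- run_toy_metadynamics(pot, n_hills = 1000, stride = 250, width = 0.05,
                              initial_height = 1e-9, reduced_height = 1e-9,
                              switch_after = 1, seed = 3, record_every = 5)
  v <- var(run$colvar$x)
  expect_lt(abs(v - kB_kcal_mol() * 300 / 10) / (kB_kcal_mol() * 300 / 10), 0.1)
})

test_that("toy metadynamics is reproducible and escapes the double well", {
  run1 <- toy_double_well_run(seed = 7)
  run2 <- toy_double_well_run(seed = 7)
  expect_identical(run1$colvar, run2$colvar)
  expect_identical(as.data.frame(run1$hills), as.data.frame(run2$hills))
  # both basins visited
  expect_true(any(run1$colvar$x < -0.7) && any(run1$colvar$x > 0.7))
  expect_gte(run1$n_recross, 2)
  # FEL barrier estimate within 20% of the analytic barrier
  grid <- seq(-1.5, 1.5, length.out = 301)
  fel <- reconstruct_fel(run1$hills, list(x = grid))
  f_r <- min(fel$fel[grid < -0.5])
  f_ts <- max(fel$fel[abs(grid) < 0.5])
  expect_lt(abs((f_ts - f_r) - 5) / 5, 0.2)
})

test_that("diverging trajectories abort with a diagnostic", {
  expect_error(toy_potential("harmonic", k = -5), "positive")
  # a wildly unstable Euler step overshoots and must be caught
  expect_error(
    run_toy_metadynamics(toy_potential("double_well", barrier = 5), x0 = 1.2,
                         n_hills = 50, stride = 100, timestep = 1e5,
                         width = 0.1, seed = 1),
    "diverged")
})

test_that("basin free-energy difference equalizes for a symmetric well", {
  # near-ideal sampling regime: small hills, fast diffusion
  run <- run_toy_metadynamics(
    toy_potential("double_well", barrier = 5), x0 = -1,
    n_hills = 3000, width = 0.15, seed = 7, friction = 0.05,
    timestep = 0.25, stride = 100,
    initial_height = 0.1, reduced_height = 0.05, switch_after = 599)
  fel <- reconstruct_fel(run$hills, list(x = seq(-1.6, 1.6, length.out = 161)),
                         basins = list(r = c(-1.3, -0.7), p = c(0.7, 1.3)),
                         trace_every = 25)
  conv <- attr(fel, "convergence")
  late <- conv$delta_f[conv$n_hills > 1500]
  # trace enters and stays within the band once both wells are filled
  expect_lt(max(abs(late)), 0.75)
  # reconstructed inter-minimum free-energy difference near the analytic 0
  expect_lt(abs(conv$delta_f[nrow(conv)]), 0.5)
})

test_that("triwell toy potential is sampled across its three wells", {
  run <- run_toy_metadynamics(
    toy_potential("triwell", barrier = 3, width = 0.5), n_hills = 600,
    stride = 100, width = c(0.15, 0.15), seed = 5,
    initial_height = 0.4, reduced_height = 0.2, switch_after = 300)
  ang <- (atan2(run$colvar$y, run$colvar$x) * 180 / pi) %% 360
  r <- sqrt(run$colvar$x^2 + run$colvar$y^2)
  near <- function(a0) any(abs(((ang - a0 + 180) %% 360) - 180) < 30 & r > 0.5)
  expect_true(near(90) && near(210) && near(330))
})
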