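test_that("the integrator reproduces closed-form solutions", {
  free <- power_series_family(alpha = 2, C2 = 0.5)
  tr <- integrate_eom(free, 3, 2, seq(0, 1, 1e-3))
  expect_equal(tr$positions[length(tr$positions)], 5, tolerance = 1e-9)

  # infall from rest under m qddot = -2k/q^3: q(t) = sqrt(1 - 2 t^2)
  # (substitution check: qddot = -2 (1 - 2t^2)^(-3/2) = -2/q^3)
  cube <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  tr <- integrate_eom(cube, 1, 0, seq(0, 0.25, 1e-3))
  expect_equal(tr$positions[length(tr$positions)], sqrt(1 - 2 * 0.25^2),
               tolerance = 1e-6)
  expect_equal(tr$positions, inverse_cube_exact(tr$times, 1, 0),
               tolerance = 1e-8)
  # and against the general closed form on an escaping path
  tr2 <- integrate_eom(cube, 1, 1.5, seq(0, 2, 1e-3))
  expect_equal(tr2$positions, inverse_cube_exact(tr2$times, 1, 1.5),
               tolerance = 1e-8)
})

test_that("energy is conserved along undriven integrations", {
  set.seed(81)
  fam <- power_series_family(alpha = 2, delta = 0.4, C0 = 1, C2 = 0.5,
                             C3 = 0.1)
  tr <- integrate_eom(fam, 1, 1.2, seq(0, 1, 1e-3))
  H <- vapply(seq_along(tr$times), function(i)
    hamiltonian(fam, tr$positions[i], tr$velocities[i]), numeric(1))
  expect_lt(max(abs(H - H[1])) / abs(H[1]), 1e-8)
})

test_that("halving the step shrinks the error ~16-fold (RK4 order)", {
  cube <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  exact <- inverse_cube_exact(1, 1, 1.5)
  e1 <- abs(integrate_eom(cube, 1, 1.5, seq(0, 1, 0.02))$positions[51] -
              exact)
  e2 <- abs(integrate_eom(cube, 1, 1.5, seq(0, 1, 0.01))$positions[101] -
              exact)
  expect_gt(e1 / e2, 12)
  expect_lt(e1 / e2, 20)
})

test_that("collisions truncate and flag the trajectory", {
  cube <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  # q = sqrt(1 - 2 t^2) reaches the origin at t = 1/sqrt(2)
  tr <- integrate_eom(cube, 1, 0, seq(0, 1, 1e-3))
  expect_false(tr$complete)
  expect_equal(tr$termination, "collision")
  expect_lt(max(tr$times), 1 / sqrt(2) + 1e-3)
  expect_gt(max(tr$times), 0.69)
  expect_error(integrate_eom(cube, 1, 0, seq(0, 1, 1e-3), error = TRUE),
               "collision")
})

test_that("planar central-force orbits behave as advertised", {
  # circular Kepler orbit: radius constant over one period
  tr <- simulate_particle_2d("inverse_square", m = 1, k = 1, x0 = 1, y0 = 0,
                             vx0 = 0, vy0 = 1,
                             t_grid = seq(0, 2 * pi, length.out = 400),
                             n_substeps = 4)
  r <- sqrt(rowSums(tr$positions^2))
  expect_lt(max(abs(r - 1)), 1e-6)

  # inward Cotes spiral on the pure branch: log r affine in the polar angle
  fx <- make_fixture("spiral_2d", seed = 1)
  r <- sqrt(rowSums(fx$truth$positions^2))
  th <- atan2(fx$truth$positions[, 2], fx$truth$positions[, 1])
  for (i in 2:length(th))
    while (th[i] < th[i - 1] - pi) th[i] <- th[i] + 2 * pi
  expect_true(all(diff(r) < 0))
  fit <- stats::lm(log(r) ~ th)
  expect_lt(max(abs(stats::resid(fit))), 1e-3)

  # angular momentum conserved under both force laws
  for (b in list(tr, fx$truth)) {
    L <- b$positions[, 1] * b$velocities[, 2] -
      b$positions[, 2] * b$velocities[, 1]
    expect_lt(max(abs(L - L[1])) / abs(L[1]), 1e-8)
  }
})

test_that("zero noise collapses observations to the deterministic path", {
  fam <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  ssm <- state_space_model(fam, process_noise_sd = c(0, 0),
                           obs_noise_sd = 0, dt = 0.01, n_samples = 100)
  sim <- simulate_observations(ssm, 1, 1.5, seed = 5)
  det <- integrate_eom(fam, 1, 1.5, sim$times, n_substeps = 2L)
  expect_identical(sim$y, det$positions)
})

test_that("observation noise has the requested sd and is reproducible", {
  free <- power_series_family(alpha = 2, C2 = 0.5)
  ssm <- state_space_model(free, obs_noise_sd = 0.3, dt = 0.01,
                           n_samples = 10000)
  sim <- simulate_observations(ssm, 5, 0, seed = 9)
  expect_equal(stats::sd(sim$y - sim$truth$positions), 0.3,
               tolerance = 0.05 * 0.3 / 0.3)
  sim2 <- simulate_observations(ssm, 5, 0, seed = 9)
  expect_identical(sim$y, sim2$y)
  sim3 <- simulate_observations(ssm, 5, 0, seed = 10)
  expect_false(identical(sim$y, sim3$y))
})

test_that("smoothed noise keeps its sd and gains autocorrelation", {
  free <- power_series_family(alpha = 2, C2 = 0.5)
  ssm <- state_space_model(free, obs_noise_sd = 0.3, noise_smoothness = 0.05,
                           dt = 0.01, n_samples = 8000)
  sim <- simulate_observations(ssm, 5, 0, seed = 11)
  eps <- sim$y - sim$truth$positions
  expect_equal(stats::sd(eps), 0.3, tolerance = 0.05)
  expect_gt(stats::cor(eps[-1], eps[-length(eps)]), 0.5)
})

test_that("process noise perturbs the latent path smoothly", {
  free <- power_series_family(alpha = 2, C2 = 0.5)
  ssm <- state_space_model(free, process_noise_sd = c(0, 0.2),
                           noise_smoothness = 0.05, dt = 0.01,
                           n_samples = 500)
  sim <- simulate_observations(ssm, 5, 0, seed = 12)
  det <- integrate_eom(free, 5, 0, sim$times, n_substeps = 2L)
  expect_gt(stats::sd(sim$truth$positions - det$positions), 0)
})

test_that("delta_sweep spans the deviation range and matches oracles", {
  base <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  tg <- seq(0, 1.5, 1e-3)
  sw <- delta_sweep(base, c(-1.5, 0, 1.5), 1, 1.5, tg)
  expect_named(sw, c("-1.5", "0", "1.5"))
  expect_identical(sw[["0"]]$times, tg)
  expect_identical(sw[["0"]]$positions,
                   integrate_eom(base, 1, 1.5, tg)$positions)
  # delta = 1 entry against an independently derived Euler-Lagrange
  # integration of L = C0 q^-1 + C2 q qdot^2
  sw1 <- delta_sweep(base, 1, 1, 1.5, tg)[["1"]]
  expect_equal(sw1$positions, rk4_delta1_oracle(1, 0.5, 1, 1.5, tg),
               tolerance = 1e-10)
  # a failing delta reports its error but does not break the sweep
  sw2 <- delta_sweep(base, c(0, -30), 1, 0.2, seq(0, 2, 1e-3))
  expect_s3_class(sw2[["0"]], "trajectory")
  expect_true(is.character(sw2[["-30"]]) || !sw2[["-30"]]$complete)
})

test_that("rescaled solutions of any family member solve the dynamics,
          but only delta = 0 keeps the action (and N) invariant", {
  # every member is scale-FREE: all its terms scale uniformly (by
  # lambda^(delta - alpha)), so the action of a rescaled path changes by a
  # path-independent constant and stationarity is preserved.  delta only
  # controls whether that constant is 1 (scale SYMMETRY).
  tg <- seq(0, 1, 1e-3)
  lam <- 2
  for (delta in c(0, 0.8)) {
    fam <- power_series_family(alpha = 2, delta = delta, C0 = 1, C2 = 0.5)
    tr <- integrate_eom(fam, 1, 1.5, tg)
    sc <- scale_trajectory(tr, scale_transform(lam, 2))
    re <- integrate_eom(fam, sc$positions[1], sc$velocities[1], sc$times,
                        n_substeps = 4L)
    expect_lt(max(abs(re$positions - sc$positions)), 1e-6)
  }
  # what does break for delta != 0 is the symmetry condition itself
  dev <- power_series_family(alpha = 2, delta = 0.8, C0 = 1, C2 = 0.5)
  pts <- data.frame(q = c(0.5, 1, 2), qdot = c(0, 1, -1), t = c(0, 1, 2))
  expect_gt(symmetry_defect(dev, scale_transform(lam, 2), pts), 1e-2)
})

test_that("fixtures are reproducible and carry their ground truth", {
  fx <- make_fixture("symmetric_1d", seed = 1)
  ns <- noether_series(fx$family, fx$truth)
  expect_lt(ns$drift, 1e-6)

  fs <- make_fixture("scalefree_1d", seed = 1)
  expect_gt(noether_series(fs$family, fs$truth)$drift, 0.05)

  d1 <- tempfile(); d2 <- tempfile()
  b1 <- make_fixture("noisy_scalefree", seed = 4, dir = d1)
  b2 <- make_fixture("noisy_scalefree", seed = 4, dir = d2)
  for (f in basename(b1$files))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "noisy_scalefree_meta.json")))
  expect_error(make_fixture("no_such_fixture", 1), "unknown fixture")
})
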