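# short, fast synthetic dataset shared across inference tests
make_short_data <- function(delta = 0, seed = 1, n = 120, noise = 0.01,
                            q0 = 1, v0 = 1.5) {
  fam <- power_series_family(alpha = 2, delta = delta, C0 = 1, C2 = 0.5)
  tg <- (seq_len(n) - 1) * 0.01
  clean <- integrate_eom(fam, q0, v0, tg, n_substeps = 2L)
  sigma <- noise * stats::sd(clean$positions)
  ssm <- state_space_model(fam, obs_noise_sd = sigma, dt = 0.01,
                           n_samples = n)
  simulate_observations(ssm, q0, v0, seed = seed)
}

test_that("free energy prefers the generating parameters on clean data", {
  sim <- make_short_data(noise = 0, n = 80)
  model <- model_spec(dt = 0.01)
  truth <- c(alpha = 2, delta = 0, C0 = 1, C2 = 0.5, C3 = 0, C4 = 0,
             log_q0 = 0, v0 = 1.5)
  cand <- gaussian_density(truth, 1e-4)
  pert <- truth
  pert[["C0"]] <- 1.3
  cand_p <- gaussian_density(pert, 1e-4)
  F_true <- free_energy(model, sim$times, sim$y, cand)
  F_pert <- free_energy(model, sim$times, sim$y, cand_p)
  expect_gt(F_true, F_pert)
})

test_that("with the prior as candidate, F is the pure accuracy term", {
  # complexity = KL(prior || prior) = 0, so F must double (within 10%)
  # when the data length doubles on a stationary residual series
  free <- power_series_family(alpha = 2, C2 = 0.5)
  model <- model_spec(dt = 0.01, init_state = "fixed", q0 = 5, v0 = 0)
  ssm <- state_space_model(free, obs_noise_sd = 0.5, dt = 0.01,
                           n_samples = 400)
  sim <- simulate_observations(ssm, 5, 0, seed = 3)
  # candidate mean = free particle at the true initial state: residuals are
  # i.i.d. noise around zero, the stationary case
  cand <- model$prior
  cand$mean[c("alpha", "C2")] <- c(2, 0.5)
  F1 <- free_energy(model, sim$times[1:200], sim$y[1:200], cand)
  F2 <- free_energy(model, sim$times, sim$y, cand)
  expect_lt(abs(F2 / F1 - 2), 0.1)
})

test_that("accepted free-energy steps are monotone and the posterior is SPD", {
  sim <- make_short_data(seed = 2)
  inv <- invert_model(sim$times, sim$y)
  expect_true(all(diff(inv$F_trace) >= 0))
  S <- inv$posterior$cov
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_length(inv$predicted, length(sim$y))
  expect_true(is.finite(inv$free_energy))
})

test_that("inversion rejects pathological data", {
  expect_error(invert_model(1:5, rep(1, 5)), "10")
})

test_that("model reduction with an unchanged prior is the identity", {
  prior <- gaussian_density(c(a = 0, b = 0), c(1, 1))
  post <- gaussian_density(c(a = 0.4, b = -0.2),
                           matrix(c(0.2, 0.05, 0.05, 0.3), 2))
  red <- bayesian_model_reduction(prior, post, prior)
  expect_equal(red$delta_F, 0, tolerance = 1e-10)
  expect_equal(red$posterior_reduced$mean, post$mean, tolerance = 1e-10)
  expect_equal(red$posterior_reduced$cov, post$cov, tolerance = 1e-10)
  bad <- gaussian_density(c(a = 0), 1)
  expect_error(bayesian_model_reduction(prior, post, bad), "names")
})

test_that("model reduction matches brute-force quadrature on toys", {
  set.seed(7)
  # 1-parameter conjugate toy
  s2 <- 0.25
  x <- rnorm(12)
  y <- x * 0.7 + rnorm(12, 0, sqrt(s2))
  P <- sum(x^2) / s2 + 1
  post <- gaussian_density(c(b = (sum(x * y) / s2) / P), 1 / P)
  prior <- gaussian_density(c(b = 0), 1)
  prior_red <- gaussian_density(c(b = 0.2), 0.03)
  dF_or <- toy_log_evidence_1d(x, y, s2, 0.2, 0.03) -
    toy_log_evidence_1d(x, y, s2, 0, 1)
  dF <- bayesian_model_reduction(prior, post, prior_red)$delta_F
  expect_equal(dF, dF_or, tolerance = 1e-6)

  # 2-parameter toy with a pinned coordinate (the delta-style reduction)
  X <- cbind(rnorm(12), rnorm(12))
  y2 <- X %*% c(0.5, -0.3) + rnorm(12, 0, sqrt(s2))
  Pm <- crossprod(X) / s2 + diag(2)
  mm <- solve(Pm, crossprod(X, y2) / s2)
  post2 <- gaussian_density(c(b1 = mm[1], b2 = mm[2]), solve(Pm))
  prior2 <- gaussian_density(c(b1 = 0, b2 = 0), c(1, 1))
  prior2r <- gaussian_density(c(b1 = 0, b2 = 0), c(1, 1e-4))
  dF2_or <- toy_log_evidence_2d(X, y2, s2, c(0, 0), c(1, 1e-4)) -
    toy_log_evidence_2d(X, y2, s2, c(0, 0), c(1, 1))
  dF2 <- bayesian_model_reduction(prior2, post2, prior2r)$delta_F
  expect_equal(dF2, dF2_or, tolerance = 1e-6)
  # the pinned coordinate collapses onto its reduced prior
  red2 <- bayesian_model_reduction(prior2, post2, prior2r)
  expect_lt(abs(red2$posterior_reduced$mean[["b2"]]), 1e-2)
  expect_lt(red2$posterior_reduced$cov["b2", "b2"], 1.1e-4)
})

test_that("model probabilities normalise correctly under both methods", {
  expect_equal(unname(model_probabilities(3, 3)), c(0.5, 0.5))
  expect_equal(suppressWarnings(
    unname(model_probabilities(-5, -5, "ratio"))), c(0.5, 0.5))
  p <- model_probabilities(log(3), 0)
  expect_equal(unname(p), c(0.75, 0.25))
  expect_equal(sum(p), 1)
  # stable far in the tails
  expect_equal(unname(model_probabilities(-1000, -1100)), c(1, 0))
  # the raw-ratio normalisation inverts preference for negative F
  expect_warning(pn <- model_probabilities(-10, -30, "ratio"),
                 "inverts")
  expect_equal(unname(pn), c(0.25, 0.75))
  expect_error(model_probabilities(-1, 2, "ratio"), "same sign")
})

test_that("classification returns a coherent report on a fixture", {
  fx <- make_fixture("noisy_symmetric", seed = 3)
  fit <- classify_symmetry(fx$times, fx$observed,
                           control = list(max_iter = 40))
  expect_s3_class(fit, "scalesym_fit")
  expect_equal(sum(fit$probabilities), 1)
  expect_true(fit$decision %in%
                c("scale-symmetric", "scale-free", "undetermined"))
  expect_equal(fit$F_reduced - fit$F_full, fit$delta_F)
  # the reduced posterior pins the deviation exponent
  expect_lt(abs(coef(fit, reduced = TRUE)[["delta"]]), 1e-3)
  # the reduced-posterior trajectory conserves its Noether charge
  expect_lt(fit$noether$reduced$drift, 1e-2)
  # methods
  expect_length(residuals(fit), length(fx$observed))
  expect_length(predict(fit), length(fx$observed))
  expect_equal(length(coef(fit)), 8L)
  s <- summary(fit)
  expect_s3_class(s, "summary.scalesym_fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(length(fx$observed), 2L))
})

test_that("pooling trials on different energy shells identifies delta", {
  # one trial leaves the deviation exponent on a flat likelihood ridge (the
  # data sit on a single energy shell); three shells remove the ambiguity
  ics <- list(c(1, 1.5), c(0.8, 1.8), c(1.5, 1.0))
  tg <- (0:199) * 0.01
  gen <- function(delta, seed) {
    lapply(seq_along(ics), function(i) {
      fam <- power_series_family(alpha = 2, delta = delta, C0 = 1, C2 = 0.5)
      clean <- integrate_eom(fam, ics[[i]][1], ics[[i]][2], tg,
                             n_substeps = 2L)
      ssm <- state_space_model(fam,
                               obs_noise_sd = 0.01 * stats::sd(clean$positions),
                               dt = 0.01, n_samples = 200)
      simulate_observations(ssm, ics[[i]][1], ics[[i]][2],
                            seed = seed * 100 + i)$y
    })
  }
  inv1 <- invert_model(tg, gen(1, 1))
  expect_equal(inv1$n_trials, 3L)
  expect_length(inv1$predicted, 3L)
  expect_true(all(c("log_q0_1", "v0_3") %in% names(inv1$posterior$mean)))
  d <- inv1$posterior$mean[["delta"]]
  sd_d <- sqrt(inv1$posterior$cov["delta", "delta"])
  # delta = 1 data: zero is excluded at 2 posterior sd
  expect_gt(d - 2 * sd_d, 0)
  expect_true(all(diff(inv1$F_trace) >= 0))
})

test_that("the Noether parameter map covers the family grid", {
  free <- power_series_family(alpha = 2, C2 = 0.5)
  one <- noether_parameter_map(free, list(alpha = 2),
                               state = c(q = 3, qdot = 2, t = 0))
  expect_equal(one$N, 6)   # m qdot (q - qdot t)

  # at qdot = 0 and t = 0 the charge is independent of every coefficient
  # multiplying a positive velocity power
  cube <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
  m <- noether_parameter_map(cube, list(C3 = seq(-1, 1, 0.5)),
                             state = c(q = 1, qdot = 0, t = 0))
  expect_equal(length(unique(m$N)), 1L)

  g <- noether_parameter_map(cube,
                             list(alpha = c(1.5, 2, 2.5),
                                  C0 = c(0.5, 1, 2)),
                             state = c(q = 1.2, qdot = 0.4, t = 1),
                             normalise = TRUE)
  expect_equal(nrow(g), 9L)
  expect_equal(max(abs(g$N), na.rm = TRUE), 1)
  expect_error(noether_parameter_map(cube, list(bogus = 1:3)), "named")
})
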