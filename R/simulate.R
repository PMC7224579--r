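#' State-space generative model for observed series
#'
#' Wraps an undriven power-series family into the stochastic state-space
#' form used for inference:
#' \deqn{\dot q = v + \omega_f^{(x)},\qquad
#'       \dot v = f(q, v) + \omega_f^{(\dot x)},\qquad
#'       y = q + \omega_g,}
#' where \eqn{f} is the family's closed-form acceleration.  The random
#' fluctuations are smooth (non-Markovian): white Gaussian draws are
#' convolved with a unit-variance-preserving Gaussian kernel of width
#' `noise_smoothness` (in time units) before being scaled to the requested
#' standard deviations, so neighbouring samples are correlated.  Setting all
#' noise standard deviations to zero recovers the deterministic trajectory
#' exactly.
#'
#' @param family An undriven [lagrangian_family()].
#' @param process_noise_sd Length-2 non-negative vector: fluctuation sd on
#'   the position and velocity equations.
#' @param obs_noise_sd Non-negative observation noise sd.
#' @param noise_smoothness Temporal correlation width of the fluctuations,
#'   in time units (0 = white).
#' @param dt Sampling interval.
#' @param n_samples Number of samples.
#' @return An object of class `state_space_model`.
#' @export
state_space_model <- function(family, process_noise_sd = c(0, 0),
                              obs_noise_sd = 0, noise_smoothness = 0,
                              dt, n_samples) {
  stopifnot(dt > 0, n_samples >= 2, all(process_noise_sd >= 0),
            obs_noise_sd >= 0, noise_smoothness >= 0)
  if (length(process_noise_sd) == 1L)
    process_noise_sd <- rep(process_noise_sd, 2)
  structure(list(family = family, process_noise_sd = process_noise_sd,
                 obs_noise_sd = obs_noise_sd,
                 noise_smoothness = noise_smoothness,
                 dt = dt, n_samples = as.integer(n_samples)),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf(
    "State-space model: %d samples, dt = %g\n", x$n_samples, x$dt))
  cat(sprintf("  process noise sd = (%g, %g), obs noise sd = %g, smoothness = %g\n",
              x$process_noise_sd[1], x$process_noise_sd[2], x$obs_noise_sd,
              x$noise_smoothness))
  print(x$family)
  invisible(x)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# n smooth Gaussian draws: white noise convolved with a Gaussian kernel of
# sd = smoothness/dt samples, renormalised so the marginal sd equals `sd`
smooth_noise <- function(n, sd, smoothness, dt) {
  if (sd == 0) return(numeric(n))
  if (smoothness <= 0) return(stats::rnorm(n, 0, sd))
  ks <- smoothness / dt
  half <- max(1L, ceiling(4 * ks))
  kern <- stats::dnorm(seq(-half, half), 0, ks)
  kern <- kern / sqrt(sum(kern^2))      # unit output variance for white input
  w <- stats::rnorm(n + 2L * half)
  sd * as.numeric(stats::filter(w, kern, sides = 2))[(half + 1L):(half + n)]
}

#' Simulate observations from a state-space model
#'
#' Integrates the (possibly noise-driven) state equations with fixed-step
#' RK4 and adds observation noise.  The process fluctuations are generated
#' on the sampling grid and linearly interpolated inside Runge-Kutta
#' stages.  The same seed always yields the identical series.
#'
#' @param ssm A [state_space_model()].
#' @param q0,v0 Initial state (`q0 > 0`).
#' @param seed Integer seed (mandatory: every stochastic call is seeded).
#' @param r_min Collision guard passed to the integrator.
#' @return A list with `times`, `y` (observed series), `truth` (the latent
#'   [trajectory()]), and `seed`.
#' @export
simulate_observations <- function(ssm, q0, v0, seed, r_min = 1e-3) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  times <- (seq_len(ssm$n_samples) - 1L) * ssm$dt
  with_seed(seed, {
    w1 <- smooth_noise(ssm$n_samples, ssm$process_noise_sd[1],
                       ssm$noise_smoothness, ssm$dt)
    w2 <- smooth_noise(ssm$n_samples, ssm$process_noise_sd[2],
                       ssm$noise_smoothness, ssm$dt)
    wg <- smooth_noise(ssm$n_samples, ssm$obs_noise_sd,
                       ssm$noise_smoothness, ssm$dt)
    truth <-
      if (all(ssm$process_noise_sd == 0)) {
        integrate_eom(ssm$family, q0, v0, times, n_substeps = 2L,
                      r_min = r_min)
      } else {
        f1 <- stats::approxfun(times, w1, rule = 2)
        f2 <- stats::approxfun(times, w2, rule = 2)
        accel <- make_accel(ssm$family)
        res <- rk4_engine(
          function(t, s) c(s[2] + f1(t), accel(s[1], s[2]) + f2(t)),
          c(q0, v0), times, n_substeps = 2L,
          guard = function(s) if (s[1] < r_min) "collision" else NULL)
        if (res$n_kept < 2L)
          stop("state integration failed on the first step")
        trajectory(times[seq_len(res$n_kept)], res$states[, 1],
                   res$states[, 2],
                   complete = res$n_kept == length(times),
                   termination = res$termination)
      }
    n <- length(truth$times)
    if (n < ssm$n_samples)
      warning("state integration truncated at t = ", truth$times[n],
              " (", truth$termination, ")")
    list(times = truth$times, y = truth$positions + wg[seq_len(n)],
         truth = truth, seed = seed)
  })
}

#' Integrate one family across a sweep of deviation exponents
#'
#' Runs [integrate_eom()] for each value of \eqn{\delta} from the same
#' initial state and grid, showing the transition from scale freeness
#' (\eqn{\delta < 0}) through scale symmetry (\eqn{\delta = 0}) and back
#' (\eqn{\delta > 0}).  Failures for individual \eqn{\delta} values are
#' collected, not fatal.
#'
#' @param base_family An undriven [lagrangian_family()]; its `delta` is
#'   replaced by each sweep value.
#' @param delta_values Numeric vector of deviation exponents.
#' @param q0,v0,t_grid,n_substeps,r_min As in [integrate_eom()].
#' @return A named list (names = delta values) whose elements are
#'   [trajectory()] objects, or `try-error`-like character messages for
#'   values that failed.
#' @export
delta_sweep <- function(base_family, delta_values, q0, v0, t_grid,
                        n_substeps = 1L, r_min = 1e-3) {
  out <- lapply(delta_values, function(d) {
    fam <- base_family
    fam$delta <- d
    tryCatch(integrate_eom(fam, q0, v0, t_grid, n_substeps = n_substeps,
                           r_min = r_min),
             error = function(e) conditionMessage(e))
  })
  names(out) <- as.character(delta_values)
  out
}

# study-condition definitions of the packaged fixtures; the inverse-cube
# (delta = 0) and inverse-square-potential (delta = 1) families use
# m = 2*C2 = 1, k = C0 = 1.  10 s of data at 200 samples matches the trial
# layout the inference defaults are designed for.
fixture_defs <- function() {
  fam0 <- power_series_family(alpha = 2, delta = 0, C0 = 1, C2 = 0.5)
  fam1 <- power_series_family(alpha = 2, delta = 1, C0 = 1, C2 = 0.5)
  base1d <- list(q0 = 1, v0 = 1.5, dt = 0.01, n = 200L)
  ell2 <- 1.8                     # spiral angular momentum^2 < 2 m k
  om <- sqrt(2 / ell2 - 1)        # inward logarithmic-spiral pitch
  list(
    symmetric_1d = c(list(kind = "1d", family = fam0, obs_rel_sd = 0,
                          smoothness = 0), base1d),
    scalefree_1d = c(list(kind = "1d", family = fam1, obs_rel_sd = 0,
                          smoothness = 0), base1d),
    noisy_symmetric = c(list(kind = "1d", family = fam0, obs_rel_sd = 0.01,
                             smoothness = 0), base1d),
    noisy_scalefree = c(list(kind = "1d", family = fam1, obs_rel_sd = 0.01,
                             smoothness = 0), base1d),
    spiral_2d = list(kind = "2d", force_law = "inverse_cube", m = 1, k = 1,
                     x0 = 1, y0 = 0, vx0 = -om * sqrt(ell2),
                     vy0 = sqrt(ell2), dt = 1 / 399, n = 400L),
    ellipse_2d = list(kind = "2d", force_law = "inverse_square", m = 1,
                      k = 1, x0 = 1, y0 = 0, vx0 = 0, vy0 = 0.9,
                      dt = 2 * pi * (1 / (2 - 0.81))^1.5 / 499, n = 500L))
}

#' Packaged ground-truth fixtures
#'
#' Reproducible simulation bundles with known generating parameters:
#' `symmetric_1d` (scale-symmetric inverse-cube family, \eqn{\delta = 0},
#' noiseless), `scalefree_1d` (the \eqn{\delta = 1} member, noiseless),
#' `noisy_symmetric` / `noisy_scalefree` (the same with smooth observation
#' noise at 1% of the signal sd), `spiral_2d` (planar inverse-cube particle
#' started on the inward logarithmic-spiral branch,
#' \eqn{\ell^2 < 2mk}), and `ellipse_2d` (planar Kepler particle over one
#' orbital period).  Initial conditions and noise levels are stored in the
#' bundle metadata.  The same name and seed always reproduce the identical
#' bundle.
#'
#' @param name Fixture name (see above).
#' @param seed Integer seed.
#' @param dir Optional directory: if given, the observed series
#'   (`<name>_data.csv`), metadata (`<name>_meta.json`) and, for 1D
#'   fixtures, the ground-truth trajectory (`<name>_truth.csv`) are written
#'   there.
#' @return A list with `name`, `times`, `observed` (vector, or matrix for
#'   planar fixtures), `truth` (a [trajectory()]), `family` (1D fixtures),
#'   `meta` (generating parameters, noise, seed), and `files` (when `dir`
#'   is given).
#' @export
make_fixture <- function(name, seed, dir = NULL) {
  defs <- fixture_defs()
  if (!name %in% names(defs))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(defs), collapse = ", "))
  def <- defs[[name]]
  if (def$kind == "1d") {
    clean <- integrate_eom(def$family, def$q0, def$v0,
                           (seq_len(def$n) - 1L) * def$dt, n_substeps = 2L)
    sigma <- def$obs_rel_sd * stats::sd(clean$positions)
    ssm <- state_space_model(def$family, process_noise_sd = c(0, 0),
                             obs_noise_sd = sigma,
                             noise_smoothness = def$smoothness,
                             dt = def$dt, n_samples = def$n)
    sim <- simulate_observations(ssm, def$q0, def$v0, seed = seed)
    bundle <- list(name = name, times = sim$times, observed = sim$y,
                   truth = sim$truth, family = def$family,
                   meta = list(name = name, seed = seed,
                               family = unclass(def$family),
                               q0 = def$q0, v0 = def$v0, dt = def$dt,
                               n_samples = def$n, obs_noise_sd = sigma,
                               noise_smoothness = def$smoothness))
  } else {
    times <- (seq_len(def$n) - 1L) * def$dt
    tr <- simulate_particle_2d(def$force_law, def$m, def$k, def$x0, def$y0,
                               def$vx0, def$vy0, times, n_substeps = 2L)
    bundle <- list(name = name, times = tr$times, observed = tr$positions,
                   truth = tr, family = NULL,
                   meta = list(name = name, seed = seed,
                               force_law = def$force_law, m = def$m,
                               k = def$k,
                               state0 = c(def$x0, def$y0, def$vx0, def$vy0),
                               dt = def$dt, n_samples = def$n))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    data_path <- file.path(dir, paste0(name, "_data.csv"))
    meta_path <- file.path(dir, paste0(name, "_meta.json"))
    if (is.matrix(bundle$observed))
      write_timeseries(data_path, bundle$times, bundle$observed[, 1],
                       bundle$observed[, 2])
    else
      write_timeseries(data_path, bundle$times, bundle$observed)
    files <- data_path
    if (def$kind == "1d") {
      truth_path <- file.path(dir, paste0(name, "_truth.csv"))
      write_timeseries(truth_path, bundle$truth$times,
                       bundle$truth$positions, bundle$truth$velocities,
                       value_name = "q", value2_name = "qdot")
      files <- c(files, truth_path)
    }
    meta <- bundle$meta
    meta$content_hash <- unname(tools::md5sum(data_path))
    atomic_write(meta_path, function(tmp)
      jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
    bundle$meta <- meta
    bundle$files <- c(files, meta_path)
  }
  bundle
}
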