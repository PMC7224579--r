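#' Deterministic trajectories on a fixed time grid
#'
#' A `trajectory` holds sampled times (fixed step `dt`), positions and
#' velocities of a 1D or planar path.  Trajectories are produced by
#' [integrate_eom()] and [simulate_particle_2d()]; an integration that hits
#' the collision guard, a singular equation of motion, or (optionally) the
#' step-doubling accuracy guard is truncated and flagged via the
#' `complete`/`termination` fields rather than silently extrapolated.
#'
#' @param times Strictly increasing times with fixed spacing.
#' @param positions Numeric vector (1D) or two-column matrix (planar).
#' @param velocities Same shape as `positions`.
#' @param complete `TRUE` if the requested grid was covered.
#' @param termination One of `"completed"`, `"collision"`, `"singular"`,
#'   `"error_tolerance"`, `"nonfinite"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, positions, velocities, complete = TRUE,
                       termination = "completed") {
  positions <- if (is.matrix(positions)) positions else as.numeric(positions)
  velocities <- if (is.matrix(velocities)) velocities else as.numeric(velocities)
  dim2 <- is.matrix(positions)
  n <- length(times)
  stopifnot(n >= 2L, all(diff(times) > 0))
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("'times' must have a fixed step")
  if (dim2) {
    stopifnot(nrow(positions) == n, nrow(velocities) == n)
    if (any(rowSums(positions^2) == 0))
      stop("planar positions must stay off the origin")
  } else {
    stopifnot(length(positions) == n, length(velocities) == n)
    if (any(positions <= 0)) stop("1D positions must stay positive")
  }
  structure(list(times = times, positions = positions,
                 velocities = velocities, dt = stats::median(dts),
                 dimensionality = if (dim2) 2L else 1L,
                 complete = complete, termination = termination),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%dD trajectory: %d samples, dt = %g, t in [%g, %g]%s\n",
              x$dimensionality, length(x$times), x$dt, min(x$times),
              max(x$times),
              if (x$complete) "" else
                sprintf(" [truncated: %s]", x$termination)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  if (x$dimensionality == 1L)
    data.frame(time = x$times, q = x$positions, qdot = x$velocities)
  else
    data.frame(time = x$times, x = x$positions[, 1], y = x$positions[, 2],
               xdot = x$velocities[, 1], ydot = x$velocities[, 2])
}

#' @export
plot.trajectory <- function(x, ...) {
  if (x$dimensionality == 1L)
    graphics::plot(x$times, x$positions, type = "l", xlab = "time",
                   ylab = "q", ...)
  else
    graphics::plot(x$positions[, 1], x$positions[, 2], type = "l",
                   xlab = "x", ylab = "y", asp = 1, ...)
  invisible(x)
}

# Fixed-step classical RK4 over a state vector.
#
# deriv(t, state) -> state derivative; guard(state) -> NULL to continue or a
# termination string.  With local_error_tol set, each step is also taken as
# two half steps and the discrepancy (scaled by 1 + |state|) must stay below
# the tolerance, otherwise integration stops with "error_tolerance".
# Returns list(states = matrix[n_kept, d], n_kept, termination).
rk4_engine <- function(deriv, state0, times, n_substeps = 1L,
                       guard = NULL, local_error_tol = NULL) {
  n <- length(times)
  d <- length(state0)
  out <- matrix(NA_real_, n, d)
  out[1, ] <- state0
  state <- state0
  termination <- "completed"
  step1 <- function(s, t, h) {
    k1 <- deriv(t, s)
    k2 <- deriv(t + h / 2, s + h / 2 * k1)
    k3 <- deriv(t + h / 2, s + h / 2 * k2)
    k4 <- deriv(t + h, s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  kept <- 1L
  for (i in 2:n) {
    h <- (times[i] - times[i - 1]) / n_substeps
    t <- times[i - 1]
    ok <- TRUE
    for (j in seq_len(n_substeps)) {
      nxt <- tryCatch(step1(state, t, h), error = function(e) e)
      if (inherits(nxt, "error")) {
        termination <- "singular"; ok <- FALSE; break
      }
      if (any(!is.finite(nxt))) {
        termination <- "nonfinite"; ok <- FALSE; break
      }
      if (!is.null(local_error_tol)) {
        half <- tryCatch(step1(step1(state, t, h / 2), t + h / 2, h / 2),
                         error = function(e) e)
        if (inherits(half, "error") || any(!is.finite(half)) ||
            max(abs(nxt - half) / (1 + abs(half))) > local_error_tol) {
          termination <- "error_tolerance"; ok <- FALSE; break
        }
      }
      if (!is.null(guard)) {
        g <- guard(nxt)
        if (!is.null(g)) {
          termination <- g; ok <- FALSE; break
        }
      }
      state <- nxt
      t <- t + h
    }
    if (!ok) break
    out[i, ] <- state
    kept <- i
  }
  list(states = out[seq_len(kept), , drop = FALSE], n_kept = kept,
       termination = termination)
}

# fast closure q'' = f(q, qdot) for an undriven family
make_accel <- function(family, singular_tol = 1e-12) {
  if (any(family$terms$z != 0))
    stop("unsupported model: integration requires an undriven family (z = 0)")
  a <- family$alpha; d <- family$delta
  tm <- family$terms[family$terms$coeff != 0, , drop = FALSE]
  if (nrow(tm) == 0L) stop("singular dynamics: all coefficients are zero")
  y <- tm$y; C <- tm$coeff
  ey <- (a - 1) * y
  anum <- C * (1 - y) * (ey + d - a)
  dsel <- y >= 2
  if (!any(dsel)) stop("singular dynamics: no term with y >= 2 has a ",
                       "nonzero coefficient")
  yd <- y[dsel]; Cd <- C[dsel]; eyd <- ey[dsel]
  ydm2 <- yd - 2
  function(q, qdot) {
    num <- sum(anum * q ^ ey * pow0(qdot, y))
    den <- sum(yd * (yd - 1) * Cd * q ^ eyd * pow0(qdot, ydm2))
    if (!is.finite(den) || abs(den) < singular_tol)
      stop("singular dynamics at q = ", q)
    num / (q * den)
  }
}

#' Integrate the equation of motion of a power-series family
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of
#' \eqn{\ddot q = f(q, \dot q)} (see [acceleration()]) from an initial state
#' on a supplied uniform time grid.  Integration stops early -- returning a
#' truncated, flagged trajectory -- if the position falls below the
#' collision guard `r_min`, if the equation of motion becomes singular, or,
#' when `local_error_tol` is set, if the per-step step-doubling error
#' estimate exceeds that tolerance (the fixed-step scheme can no longer meet
#' its accuracy contract, e.g. on approach to a collision singularity).
#'
#' @param family An undriven [lagrangian_family()].
#' @param q0 Initial position (> 0).
#' @param v0 Initial velocity.
#' @param t_grid Uniform, strictly increasing times; the first entry is the
#'   initial time.
#' @param n_substeps Internal RK4 steps per grid interval.
#' @param r_min Collision guard: positions below this abort integration.
#' @param local_error_tol Optional per-step step-doubling error tolerance.
#' @param error Throw an error (`TRUE`) or return the flagged partial
#'   trajectory (`FALSE`, default) when integration stops early.
#' @return A [trajectory()].
#' @examples
#' fam <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
#' tr <- integrate_eom(fam, q0 = 1, v0 = 1.5, t_grid = seq(0, 5, 0.01))
#' @export
integrate_eom <- function(family, q0, v0, t_grid, n_substeps = 1L,
                          r_min = 1e-3, local_error_tol = NULL,
                          error = FALSE) {
  stopifnot(q0 > 0)
  accel <- make_accel(family)
  res <- rk4_engine(
    deriv = function(t, s) c(s[2], accel(s[1], s[2])),
    state0 = c(q0, v0), times = t_grid, n_substeps = n_substeps,
    guard = function(s) if (s[1] < r_min) "collision" else NULL,
    local_error_tol = local_error_tol)
  if (res$n_kept < length(t_grid) && error)
    stop("integration stopped at t = ", t_grid[res$n_kept], " (",
         res$termination, ")")
  if (res$n_kept < 2L)
    stop("integration failed on the first step (", res$termination,
         ") at t = ", t_grid[1])
  trajectory(t_grid[seq_len(res$n_kept)], res$states[, 1], res$states[, 2],
             complete = res$n_kept == length(t_grid),
             termination = res$termination)
}

#' Simulate a planar particle under a central force law
#'
#' Integrates \eqn{m\ddot{\mathbf r} = F(r)\hat{\mathbf r}} with
#' \eqn{F = -2k/r^3} (`"inverse_cube"`, from the scale-symmetric potential
#' \eqn{V = -k r^{-2}}; the resulting bound paths are logarithmic/Cotes
#' spirals) or \eqn{F = -k/r^2} (`"inverse_square"`, the Kepler force whose
#' bound paths are ellipses).  Angular momentum
#' \eqn{\ell = m(x\dot y - y\dot x)} is conserved by the dynamics and
#' serves as an integration-quality check.
#'
#' @param force_law `"inverse_cube"` or `"inverse_square"`.
#' @param m Particle mass.
#' @param k Force-law constant (> 0 is attractive).
#' @param x0,y0,vx0,vy0 Initial state; the initial point must be off the
#'   origin.
#' @param t_grid Uniform, strictly increasing times.
#' @param n_substeps Internal RK4 steps per grid interval.
#' @param r_min Collision guard radius.
#' @param error As in [integrate_eom()].
#' @return A planar [trajectory()].
#' @export
simulate_particle_2d <- function(force_law = c("inverse_cube",
                                               "inverse_square"),
                                 m = 1, k = 1, x0, y0, vx0, vy0, t_grid,
                                 n_substeps = 1L, r_min = 1e-3,
                                 error = FALSE) {
  force_law <- match.arg(force_law)
  if (x0 == 0 && y0 == 0) stop("initial point must be off the origin")
  fmag <- switch(force_law,
                 inverse_cube = function(r) -2 * k / r^3,
                 inverse_square = function(r) -k / r^2)
  deriv <- function(t, s) {
    r <- sqrt(s[1]^2 + s[2]^2)
    f <- fmag(r) / (m * r)    # acceleration per unit position component
    c(s[3], s[4], f * s[1], f * s[2])
  }
  res <- rk4_engine(
    deriv, c(x0, y0, vx0, vy0), t_grid, n_substeps = n_substeps,
    guard = function(s)
      if (sqrt(s[1]^2 + s[2]^2) < r_min) "collision" else NULL)
  if (res$n_kept < length(t_grid) && error)
    stop("integration stopped at t = ", t_grid[res$n_kept], " (",
         res$termination, ")")
  if (res$n_kept < 2L)
    stop("integration failed on the first step (", res$termination, ")")
  trajectory(t_grid[seq_len(res$n_kept)],
             res$states[, 1:2, drop = FALSE],
             res$states[, 3:4, drop = FALSE],
             complete = res$n_kept == length(t_grid),
             termination = res$termination)
}

#' Rescale a trajectory by a scale transformation
#'
#' Maps a path \eqn{q(t)} to \eqn{q_s(t_s) = \lambda q(\lambda^{-\alpha}
#' t_s)}: times are multiplied by \eqn{\lambda^\alpha}, positions by
#' \eqn{\lambda}, velocities by \eqn{\lambda^{1-\alpha}}.  If the original
#' path solves the equation of motion of a scale-symmetric family
#' (\eqn{\delta = 0}) with the same \eqn{\alpha}, so does the rescaled
#' path; for \eqn{\delta \neq 0} it does not.
#'
#' @param trajectory A [trajectory()].
#' @param transform A [scale_transform()].
#' @return A [trajectory()].
#' @export
scale_trajectory <- function(trajectory, transform) {
  lam <- transform$lam; a <- transform$alpha
  trajectory(trajectory$times * lam ^ a,
             trajectory$positions * lam,
             trajectory$velocities * lam ^ (1 - a),
             complete = trajectory$complete,
             termination = trajectory$termination)
}
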