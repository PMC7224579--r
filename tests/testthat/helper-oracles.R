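# Independent oracle machinery used across the suite.  Everything here is
# derived from first principles (exact power-series calculus, quadrature,
# closed-form trajectories) and never calls the code paths it checks.

# Euler-Lagrange oracle: solve dL/dq - d/dt(dL/dqdot) = 0 for qddot using
# exact second partial derivatives of the undriven power series
# L = sum C_y q^(delta - alpha + y(alpha-1)) qdot^y, written independently
# of the package's closed-form acceleration.
el_acceleration_oracle <- function(family, q, qdot) {
  a <- family$alpha
  tm <- family$terms
  e <- family$delta - a + tm$y * (a - 1)
  p0 <- function(x, k) {
    out <- x ^ k
    out[k == 0] <- 1
    out
  }
  Lq <- sum(tm$coeff * e * q ^ (e - 1) * p0(qdot, tm$y))
  Lqd_q <- sum(tm$coeff * e * tm$y * q ^ (e - 1) *
                 p0(qdot, tm$y - 1) * (tm$y >= 1))
  Lqd_qd <- sum(tm$coeff * tm$y * (tm$y - 1) * q ^ e *
                  p0(qdot, tm$y - 2) * (tm$y >= 2))
  (Lq - qdot * Lqd_q) / Lqd_qd
}

# random undriven family with a well-conditioned equation of motion
random_family <- function() {
  power_series_family(
    alpha = stats::runif(1, 0.5, 3),
    delta = stats::runif(1, -1.5, 1.5),
    C0 = stats::rnorm(1),
    C2 = sample(c(-1, 1), 1) * stats::runif(1, 0.2, 1),
    C3 = stats::rnorm(1, 0, 0.3),
    C4 = stats::rnorm(1, 0, 0.3))
}

random_point <- function(qdot_nonzero = FALSE) {
  qd <- stats::runif(1, -2, 2)
  if (qdot_nonzero) qd <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 2)
  list(q = stats::runif(1, 0.3, 3), qdot = qd, t = stats::runif(1, 0.1, 5))
}

# central finite difference of a scalar function
fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# closed-form inverse-cube trajectory with m = k = 1:
# q(t)^2 = q0^2 + 2 q0 v0 t + 2 H t^2, H = v0^2/2 - q0^-2
inverse_cube_exact <- function(t, q0, v0) {
  H <- v0^2 / 2 - q0^-2
  sqrt(q0^2 + 2 * q0 * v0 * t + 2 * H * t^2)
}

# independent integration of the delta = 1 member of the alpha = 2 family
# (L = C0 q^-1 + C2 q qdot^2): Euler-Lagrange by hand gives
# qddot = -C0 / (2 C2 q^3) - qdot^2 / (2 q); plain RK4 written out here.
rk4_delta1_oracle <- function(C0, C2, q0, v0, t_grid) {
  acc <- function(q, v) -C0 / (2 * C2 * q^3) - v^2 / (2 * q)
  n <- length(t_grid)
  q <- numeric(n); v <- numeric(n)
  q[1] <- q0; v[1] <- v0
  for (i in 2:n) {
    h <- t_grid[i] - t_grid[i - 1]
    k1q <- v[i-1];            k1v <- acc(q[i-1], v[i-1])
    k2q <- v[i-1] + h/2*k1v;  k2v <- acc(q[i-1] + h/2*k1q, v[i-1] + h/2*k1v)
    k3q <- v[i-1] + h/2*k2v;  k3v <- acc(q[i-1] + h/2*k2q, v[i-1] + h/2*k2v)
    k4q <- v[i-1] + h*k3v;    k4v <- acc(q[i-1] + h*k3q, v[i-1] + h*k3v)
    q[i] <- q[i-1] + h/6*(k1q + 2*k2q + 2*k3q + k4q)
    v[i] <- v[i-1] + h/6*(k1v + 2*k2v + 2*k3v + k4v)
  }
  q
}

# log evidence of a Gaussian-likelihood toy by adaptive quadrature
toy_log_evidence_1d <- function(x, y, s2, prior_mean, prior_var) {
  f <- Vectorize(function(th)
    exp(sum(stats::dnorm(y, x * th, sqrt(s2), log = TRUE))) *
      stats::dnorm(th, prior_mean, sqrt(prior_var)))
  log(stats::integrate(f, prior_mean - 10, prior_mean + 10,
                       rel.tol = 1e-12)$value)
}

toy_log_evidence_2d <- function(X, y, s2, prior_mean, prior_var) {
  ll <- function(b1, b2)
    sum(stats::dnorm(y, X %*% c(b1, b2), sqrt(s2), log = TRUE))
  inner <- Vectorize(function(a)
    stats::integrate(Vectorize(function(b)
      exp(ll(a, b)) * stats::dnorm(b, prior_mean[2], sqrt(prior_var[2]))),
      prior_mean[2] - 8 * sqrt(prior_var[2]),
      prior_mean[2] + 8 * sqrt(prior_var[2]),
      rel.tol = 1e-10)$value *
      stats::dnorm(a, prior_mean[1], sqrt(prior_var[1])))
  log(stats::integrate(inner, prior_mean[1] - 8 * sqrt(prior_var[1]),
                       prior_mean[1] + 8 * sqrt(prior_var[1]),
                       rel.tol = 1e-10)$value)
}
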