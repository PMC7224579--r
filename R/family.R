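#' Power-series Lagrangian families with a scale-symmetry deviation exponent
#'
#' A scale transformation maps a trajectory point as
#' \eqn{(q, \dot q, t) \to (\lambda q, \lambda^{1-\alpha}\dot q,
#' \lambda^\alpha t)} for a spatial factor \eqn{\lambda > 0} and a
#' system-dependent temporal exponent \eqn{\alpha}.  A Lagrangian is
#' scale-symmetric when it scales like inverse time under this map,
#' \eqn{L \to \lambda^{-\alpha} L}.  For a power series
#' \eqn{L = \sum C_{yz}\, q^{x}\dot q^{y} t^{z}} this pins the position
#' exponent to \eqn{x = -\alpha - (1-\alpha)y - \alpha z}, so a family is
#' parameterised by \eqn{\alpha}, the coefficients \eqn{C_{yz}}, and a
#' deviation exponent \eqn{\delta} that multiplies the whole series by
#' \eqn{q^\delta}: \eqn{\delta = 0} is exactly scale-symmetric, while
#' \eqn{\delta \neq 0} is scale-free but not symmetric.
#'
#' `lagrangian_family()` builds such a family from a table of terms;
#' `power_series_family()` is a convenience wrapper for the undriven
#' fifth-order expansion used as the generative model throughout the package,
#' with coefficients named \eqn{C_0, C_1, C_2, C_3, C_4} (the velocity
#' powers).  The \eqn{C_1} term is a total time derivative: it changes the
#' Lagrangian but not the equation of motion, and is therefore excluded from
#' the default inference parameter vector.
#'
#' @param alpha Temporal scale exponent \eqn{\alpha}.
#' @param delta Deviation-from-symmetry exponent \eqn{\delta}.
#' @param terms A data frame with columns `y` (velocity power, integer
#'   \eqn{\ge 0}), `z` (explicit-time power, 0 for undriven systems) and
#'   `coeff` (real expansion coefficient).
#' @param dimensionality 1 for a scalar coordinate, 2 for the planar
#'   (radial) generalisation.
#' @return An object of class `lagrangian_family`.
#' @examples
#' free <- power_series_family(alpha = 2, C2 = 0.5)      # L = qdot^2 / 2
#' cube <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5) # + q^-2 potential
#' lagrangian_value(free, q = 1, qdot = 2, t = 0)
#' acceleration(cube, q = 1, qdot = 0)
#' @export
lagrangian_family <- function(alpha, delta = 0, terms, dimensionality = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (!dimensionality %in% c(1, 2))
    stop("'dimensionality' must be 1 or 2")
  terms <- as.data.frame(terms)
  if (!all(c("y", "z", "coeff") %in% names(terms)))
    stop("'terms' needs columns y, z, coeff")
  terms <- terms[, c("y", "z", "coeff")]
  if (any(!is.finite(terms$coeff))) stop("coefficients must be finite")
  if (any(terms$y < 0) || any(terms$y != round(terms$y)))
    stop("velocity powers 'y' must be non-negative integers")
  if (any(terms$z != round(terms$z)))
    stop("time powers 'z' must be integers")
  structure(
    list(alpha = alpha, delta = delta, terms = terms,
         dimensionality = as.integer(dimensionality)),
    class = "lagrangian_family")
}

#' @rdname lagrangian_family
#' @param C0,C1,C2,C3,C4 Coefficients of the velocity powers 0 through 4 in
#'   the undriven fifth-order expansion.
#' @export
power_series_family <- function(alpha = 2, delta = 0,
                                C0 = 0, C1 = 0, C2 = 0.5, C3 = 0, C4 = 0,
                                dimensionality = 1) {
  coeff <- c(C0, C1, C2, C3, C4)
  lagrangian_family(alpha, delta,
                    data.frame(y = 0:4, z = 0, coeff = coeff),
                    dimensionality = dimensionality)
}

#' @export
print.lagrangian_family <- function(x, ...) {
  cat(sprintf(
    "Power-series Lagrangian family (%dD): alpha = %g, delta = %g%s\n",
    x$dimensionality, x$alpha, x$delta,
    if (x$delta == 0) " (scale-symmetric)" else " (scale-free)"))
  act <- x$terms[x$terms$coeff != 0, , drop = FALSE]
  if (nrow(act) == 0L) {
    cat("  (all coefficients zero)\n")
  } else {
    ex <- term_q_exponent(x, act$y, act$z)
    for (i in seq_len(nrow(act)))
      cat(sprintf("  %+g q^%g qdot^%d%s\n", act$coeff[i], ex[i], act$y[i],
                  if (act$z[i] != 0) sprintf(" t^%d", act$z[i]) else ""))
  }
  invisible(x)
}

# effective position exponent of each term, delta included
term_q_exponent <- function(family, y, z) {
  family$delta - family$alpha + y * (family$alpha - 1) - z * family$alpha
}

check_domain <- function(family, q, t) {
  if (any(q <= 0))
    stop("domain error: the Lagrangian family is defined for q > 0 only")
  if (any(family$terms$z < 0) && any(t <= 0))
    stop("domain error: t <= 0 with a negative explicit-time power")
}

#' Evaluate a Lagrangian family and its exact partial derivatives
#'
#' `lagrangian_value()` returns
#' \eqn{L = q^{\delta-\alpha} \sum_{y,z} C_{yz}\,
#' q^{y(\alpha-1) - z\alpha}\, \dot q^{y} t^{z}}.
#' `dL_dq()` and `dL_dqdot()` are the closed-form partials of the power
#' series, the ingredients of the Euler-Lagrange equation and of the Noether
#' charge.
#'
#' @param family A [lagrangian_family()].
#' @param q Position (must be positive; the family has non-integer and
#'   negative exponents, so non-positive positions are rejected rather than
#'   silently absolute-valued).
#' @param qdot Velocity.
#' @param t Time (only enters driven families with `z != 0` terms).
#' @return A finite real number.
#' @export
lagrangian_value <- function(family, q, qdot, t = 0) {
  check_domain(family, q, t)
  tm <- family$terms
  ex <- term_q_exponent(family, tm$y, tm$z)
  sum(tm$coeff * q ^ ex * pow0(qdot, tm$y) * pow0(t, tm$z))
}

# x^k with the convention 0^0 = 1 and without NaN from 0 * 0^(-1)
pow0 <- function(x, k) {
  out <- x ^ k
  out[k == 0] <- 1
  out
}

#' @rdname lagrangian_value
#' @export
dL_dq <- function(family, q, qdot, t = 0) {
  check_domain(family, q, t)
  tm <- family$terms
  ex <- term_q_exponent(family, tm$y, tm$z)
  sum(tm$coeff * ex * q ^ (ex - 1) * pow0(qdot, tm$y) * pow0(t, tm$z))
}

#' @rdname lagrangian_value
#' @export
dL_dqdot <- function(family, q, qdot, t = 0) {
  check_domain(family, q, t)
  tm <- family$terms
  keep <- tm$y >= 1          # y = 0 terms do not depend on qdot
  tm <- tm[keep, , drop = FALSE]
  if (nrow(tm) == 0L) return(0)
  ex <- term_q_exponent(family, tm$y, tm$z)
  sum(tm$coeff * tm$y * q ^ ex * pow0(qdot, tm$y - 1) * pow0(t, tm$z))
}

#' Solve the exponent-matching condition for the position power
#'
#' For a single power-series term \eqn{C q^x \dot q^y t^z} to scale like
#' inverse time under the scale transformation, the exponents must satisfy
#' \eqn{x + (1-\alpha)y + \alpha z = -\alpha}; this returns the unique
#' solution \eqn{x = -\alpha - (1-\alpha)y - \alpha z}.
#'
#' @param alpha Temporal scale exponent.
#' @param y Velocity power.
#' @param z Explicit-time power.
#' @return The position exponent `x` (real).
#' @examples
#' solve_position_exponent(2, 2, 0)  # kinetic term: x = 0
#' solve_position_exponent(2, 0, 0)  # potential term: x = -2
#' @export
solve_position_exponent <- function(alpha, y, z = 0) {
  -alpha - (1 - alpha) * y - alpha * z
}

#' Exponents making the particle-in-a-potential Lagrangian scale-symmetric
#'
#' For \eqn{L = \tfrac12 m\dot q^2 + k q^p}, imposing
#' \eqn{L(\lambda q, \lambda^{1-\alpha}\dot q, \lambda^\alpha t) =
#' \lambda^{-\alpha} L} forces every term to carry the factor
#' \eqn{\lambda^{-\alpha}}, which yields the linear system
#' \eqn{2(1-\alpha) = -\alpha} (kinetic term) and \eqn{p = -\alpha}
#' (potential term).  The function assembles and solves that system, so the
#' exponents are computed rather than quoted: the unique solution is
#' \eqn{\alpha = 2}, \eqn{p = -2} -- an inverse-square potential, i.e. an
#' inverse-cube force.
#'
#' @return A named numeric vector with components `alpha` and `p`.
#' @examples
#' particle_symmetry_exponents()
#' @export
particle_symmetry_exponents <- function() {
  # rows: kinetic 2(1 - alpha) + alpha = 0 ; potential p + alpha = 0
  A <- rbind(c(-1, 0),
             c(1, 1))
  b <- c(-2, 0)
  sol <- solve(A, b)
  c(alpha = sol[1], p = sol[2])
}

#' Scale transformations and the symmetry condition
#'
#' `scale_transform()` represents the map
#' \eqn{(q, \dot q, t) \to (\lambda q, \lambda^{1-\alpha}\dot q,
#' \lambda^\alpha t)}.  `scaled_lagrangian_value()` evaluates the family at
#' the transformed arguments, and `symmetry_defect()` measures the worst
#' relative violation of the symmetry condition
#' \eqn{L_s = \lambda^{-\alpha} L} over a set of evaluation points: it is
#' zero (to numerical precision) exactly when the family is
#' scale-symmetric there.
#'
#' @param lam Spatial scale factor \eqn{\lambda > 0}.
#' @param alpha Temporal exponent \eqn{\alpha} of the transformation.
#' @return `scale_transform()` returns an object of class
#'   `scale_transform`; `symmetry_defect()` a non-negative scalar.
#' @examples
#' fam <- power_series_family(alpha = 2, C0 = 1, C2 = 0.5)
#' tr <- scale_transform(lam = 3.7, alpha = 2)
#' pts <- data.frame(q = c(1, 2), qdot = c(0.3, -1), t = c(0, 4))
#' symmetry_defect(fam, tr, pts)            # ~ 0: exactly symmetric
#' fam$delta <- 0.5
#' symmetry_defect(fam, tr, pts)            # > 0: symmetry broken
#' @export
scale_transform <- function(lam, alpha) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(lam = lam, alpha = alpha), class = "scale_transform")
}

#' @export
print.scale_transform <- function(x, ...) {
  cat(sprintf("Scale transformation: q -> %g q, qdot -> %g qdot, t -> %g t\n",
              x$lam, x$lam ^ (1 - x$alpha), x$lam ^ x$alpha))
  invisible(x)
}

# (q, qdot, t) image under the transform
transform_point <- function(transform, q, qdot, t) {
  list(q = transform$lam * q,
       qdot = transform$lam ^ (1 - transform$alpha) * qdot,
       t = transform$lam ^ transform$alpha * t)
}

#' @rdname scale_transform
#' @param family A [lagrangian_family()].
#' @param transform A [scale_transform()].
#' @param q,qdot,t Evaluation point (see [lagrangian_value()]).
#' @export
scaled_lagrangian_value <- function(family, transform, q, qdot, t = 0) {
  p <- transform_point(transform, q, qdot, t)
  lagrangian_value(family, p$q, p$qdot, p$t)
}

#' @rdname scale_transform
#' @param points A data frame (or matrix) of evaluation points with columns
#'   `q`, `qdot`, `t`; all `q` must be positive.
#' @param eps_abs Absolute floor in the relative defect, guarding points
#'   where the Lagrangian is close to zero.
#' @export
symmetry_defect <- function(family, transform, points, eps_abs = 1e-12) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) stop("'points' must be non-empty")
  if (is.null(points$t)) points$t <- 0
  defect <- vapply(seq_len(nrow(points)), function(i) {
    L <- lagrangian_value(family, points$q[i], points$qdot[i], points$t[i])
    Ls <- scaled_lagrangian_value(family, transform,
                                  points$q[i], points$qdot[i], points$t[i])
    ref <- transform$lam ^ (-transform$alpha) * L
    abs(Ls - ref) / (abs(ref) + eps_abs)
  }, numeric(1))
  max(defect)
}

#' Closed-form acceleration of an undriven power-series family
#'
#' Solves the Euler-Lagrange equation of the undriven (`z = 0`) family for
#' \eqn{\ddot q}:
#' \deqn{\ddot q = q^{-1}
#'   \frac{\sum_y C_y (1-y)\,((\alpha-1)y + \delta - \alpha)\,
#'         q^{(\alpha-1)y} \dot q^{y}}
#'        {\sum_{y \ge 2} y(y-1) C_y\, q^{(\alpha-1)y} \dot q^{y-2}}.}
#' For \eqn{\alpha = 2}, \eqn{\delta = 0} and only \eqn{C_0, C_2} active
#' this reduces to Newton's law for the inverse-cube force,
#' \eqn{\ddot q = -C_0/(C_2 q^3)} (i.e. \eqn{m\ddot q = -2k/q^3} with
#' \eqn{m = 2C_2}, \eqn{k = C_0}).
#'
#' @inheritParams lagrangian_value
#' @param singular_tol Smallest admissible absolute value of the
#'   denominator; below it the dynamics are reported as singular.
#' @return \eqn{\ddot q}, a finite real.
#' @export
acceleration <- function(family, q, qdot, singular_tol = 1e-12) {
  if (any(family$terms$z != 0))
    stop("unsupported model: acceleration requires an undriven family (z = 0)")
  check_domain(family, q, t = 1)
  a <- family$alpha; d <- family$delta
  tm <- family$terms
  ey <- (a - 1) * tm$y
  num <- sum(tm$coeff * (1 - tm$y) * ((a - 1) * tm$y + d - a) *
               q ^ ey * pow0(qdot, tm$y))
  den_terms <- tm$y >= 2
  den <- sum(tm$y[den_terms] * (tm$y[den_terms] - 1) * tm$coeff[den_terms] *
               q ^ ey[den_terms] * pow0(qdot, tm$y[den_terms] - 2))
  if (!is.finite(den) || abs(den) < singular_tol)
    stop("singular dynamics: the equation-of-motion denominator is ",
         "smaller than 'singular_tol' (no term with y >= 2 dominates)")
  num / (q * den)
}

#' Read and write Lagrangian families as JSON
#'
#' Families serialise to a small JSON document
#' `{alpha, delta, dimensionality, terms: [{y, z, coeff}, ...]}` with full
#' double precision, so a write-then-read round trip is exact.
#'
#' @param family A [lagrangian_family()].
#' @param path File path.
#' @return `read_family()` returns a [lagrangian_family()];
#'   `write_family()` returns `path` invisibly.
#' @export
write_family <- function(family, path) {
  doc <- list(alpha = family$alpha, delta = family$delta,
              dimensionality = family$dimensionality,
              terms = family$terms)
  atomic_write(path, function(tmp)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows"))
  invisible(path)
}

#' @rdname write_family
#' @export
read_family <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lagrangian_family(doc$alpha, doc$delta, doc$terms,
                    dimensionality = doc$dimensionality)
}
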