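#' Decide scale symmetry versus scale freeness for a time series
#'
#' The package's main fitting function.  It (i) inverts the full
#' state-space model (deviation exponent \eqn{\delta} free) on the series
#' with [invert_model()], (ii) scores the reduced, scale-symmetric model
#' (\eqn{\delta} pinned to zero by a shrinkage prior of variance
#' `epsilon_delta`) with [bayesian_model_reduction()], (iii) converts the
#' two free energies to model probabilities, and (iv) evaluates the Noether
#' charge along the trajectories implied by the full and reduced posterior
#' means, whose drift shows conservation under the symmetric model and its
#' breakdown under the scale-free one.
#'
#' @param times,y Observed series on a uniform grid.
#' @param model A [model_spec()]; defaults built from the data.
#' @param control Passed to [invert_model()]; additionally `method`
#'   (`"softmax"` or `"ratio"`, for the probabilities) and
#'   `epsilon_delta` (reduced prior variance on `delta`, default 1e-8).
#' @return An object of class `scalesym_fit` with components
#'   `F_full`, `F_reduced`, `probabilities`, `posterior_full`,
#'   `posterior_reduced`, `noether` (full/reduced [noether_series()] or
#'   `NULL` when the posterior trajectory is not integrable), `decision`
#'   (`"scale-symmetric"`, `"scale-free"` or `"undetermined"`), and the
#'   underlying `inversion`.
#' @seealso [invert_model()], [bayesian_model_reduction()],
#'   [model_probabilities()]
#' @examples
#' \donttest{
#' fx <- make_fixture("noisy_symmetric", seed = 1)
#' fit <- classify_symmetry(fx$times, fx$observed)
#' fit
#' coef(fit)["delta"]
#' }
#' @export
classify_symmetry <- function(times, y, model = NULL, control = list()) {
  method <- if (is.null(control$method)) "softmax" else control$method
  eps <- if (is.null(control$epsilon_delta)) 1e-8 else control$epsilon_delta
  control$method <- NULL
  control$epsilon_delta <- NULL
  inv <- invert_model(times, y, model, control)
  model <- inv$model   # priors extended for multi-trial data
  prior <- model$prior
  prior_red <- prior
  prior_red$mean[["delta"]] <- 0
  prior_red$cov["delta", ] <- 0
  prior_red$cov[, "delta"] <- 0
  prior_red$cov["delta", "delta"] <- eps
  red <- bayesian_model_reduction(prior, inv$posterior, prior_red)
  F_full <- inv$free_energy
  F_reduced <- F_full + red$delta_F
  probs <- model_probabilities(F_reduced, F_full, method = method)
  times1 <- if (is.list(y)) {
    if (is.list(times)) times[[1]] else times
  } else times
  noe <- list(
    full = posterior_noether(inv$posterior$mean, model, times1,
                             ntrials = inv$n_trials),
    reduced = posterior_noether(red$posterior_reduced$mean, model, times1,
                                ntrials = inv$n_trials))
  decision <- if (abs(probs[["p_reduced"]] - 0.5) < 1e-12) "undetermined"
  else if (probs[["p_reduced"]] > 0.5) "scale-symmetric" else "scale-free"
  structure(list(F_full = F_full, F_reduced = F_reduced,
                 delta_F = red$delta_F, probabilities = probs,
                 posterior_full = inv$posterior,
                 posterior_reduced = red$posterior_reduced,
                 noether = noe, decision = decision, method = method,
                 inversion = inv, times = times, y = y, model = model),
            class = "scalesym_fit")
}

# Noether series along the trajectory integrated from a posterior mean
# (first trial's initial state for multi-trial fits)
posterior_noether <- function(theta, model, times, ntrials = 1L) {
  fam <- power_series_family(alpha = theta[["alpha"]],
                             delta = theta[["delta"]],
                             C0 = theta[["C0"]], C2 = theta[["C2"]],
                             C3 = theta[["C3"]], C4 = theta[["C4"]])
  if (model$init_state == "estimated") {
    icn <- ic_names(1L, ntrials)
    q0 <- exp(theta[[icn[1]]])
    v0 <- theta[[icn[2]]]
  } else {
    q0 <- model$q0
    v0 <- model$v0
  }
  tr <- tryCatch(
    integrate_eom(fam, q0, v0, times, n_substeps = model$n_substeps,
                  r_min = model$r_min),
    error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  noether_series(fam, tr)
}

#' @export
print.scalesym_fit <- function(x, ...) {
  cat("Scale-symmetry classification\n")
  cat(sprintf("  F (scale-symmetric, delta = 0): %.3f\n", x$F_reduced))
  cat(sprintf("  F (scale-free, delta free):     %.3f\n", x$F_full))
  cat(sprintf("  p(delta = 0) = %.3f  [%s]\n", x$probabilities[["p_reduced"]],
              x$method))
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}

#' @export
summary.scalesym_fit <- function(object, ...) {
  po <- object$posterior_full
  tab <- data.frame(mean = po$mean, sd = sqrt(diag(po$cov)))
  structure(list(fit = object, parameters = tab,
                 drift_full = if (!is.null(object$noether$full))
                   object$noether$full$drift else NA_real_,
                 drift_reduced = if (!is.null(object$noether$reduced))
                   object$noether$reduced$drift else NA_real_),
            class = "summary.scalesym_fit")
}

#' @export
print.summary.scalesym_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFull-model posterior (mean +/- sd):\n")
  print(round(x$parameters, 4))
  cat(sprintf("\nNoether drift: full %.3g, reduced %.3g\n",
              x$drift_full, x$drift_reduced))
  invisible(x)
}

#' @export
coef.scalesym_fit <- function(object, reduced = FALSE, ...) {
  if (reduced) object$posterior_reduced$mean else object$posterior_full$mean
}

#' @export
predict.scalesym_fit <- function(object, reduced = FALSE, ...) {
  if (!reduced) return(object$inversion$predicted)
  trials <- as_trials(object$times, object$y)
  nt <- length(trials)
  out <- lapply(seq_len(nt), function(i)
    predict_series(object$posterior_reduced$mean, object$model,
                   trials[[i]]$times, trial = i, ntrials = nt))
  if (any(vapply(out, is.null, logical(1))))
    stop("the reduced-posterior trajectory is not integrable on the grid")
  if (nt == 1L) out[[1]] else out
}

#' @export
residuals.scalesym_fit <- function(object, ...) {
  object$inversion$residuals
}

#' @export
logLik.scalesym_fit <- function(object, ...) {
  structure(object$F_full, df = length(object$posterior_full$mean),
            class = "logLik")
}

#' @export
simulate.scalesym_fit <- function(object, nsim = 1, seed = 1, ...) {
  th <- object$posterior_full$mean
  fam <- power_series_family(alpha = th[["alpha"]], delta = th[["delta"]],
                             C0 = th[["C0"]], C2 = th[["C2"]],
                             C3 = th[["C3"]], C4 = th[["C4"]])
  sigma <- exp(-object$inversion$hyper_posterior$mean[["log_prec_y"]] / 2)
  times1 <- if (is.list(object$times)) object$times[[1]] else object$times
  dt <- stats::median(diff(times1))
  ssm <- state_space_model(fam, obs_noise_sd = sigma, dt = dt,
                           n_samples = length(times1))
  if (object$model$init_state == "estimated") {
    icn <- ic_names(1L, object$inversion$n_trials)
    q0 <- exp(th[[icn[1]]])
    v0 <- th[[icn[2]]]
  } else {
    q0 <- object$model$q0
    v0 <- object$model$v0
  }
  out <- lapply(seq_len(nsim), function(i)
    simulate_observations(ssm, q0, v0, seed = seed + i - 1)$y)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.scalesym_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$y, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "time", ylab = "y", main = "data and fitted series")
  graphics::lines(x$times, x$inversion$predicted, col = "red")
  if (!is.null(x$noether$full)) {
    graphics::plot(x$noether$full$times, x$noether$full$values, type = "l",
                   xlab = "time", ylab = "N",
                   main = "Noether charge at the posterior means")
    if (!is.null(x$noether$reduced))
      graphics::lines(x$noether$reduced$times, x$noether$reduced$values,
                      lty = 2)
    graphics::legend("topleft", legend = c("full", "reduced"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Map the Noether charge across the family's parameter space
#'
#' Evaluates the charge at a fixed state over a grid spanning two or three
#' of the family parameters (`alpha`, `delta`, `C0`, `C2`, `C3`, `C4`),
#' holding the rest at the template family's values.  Grid nodes where the
#' evaluation is undefined (domain errors) are returned as `NA` rather
#' than failing.  With `normalise = TRUE` the values are divided by the
#' maximum absolute value so they span \eqn{[-1, 1]}.
#'
#' @param family_template A [lagrangian_family()] providing the fixed
#'   parameter values (must be an undriven fifth-order expansion).
#' @param grid Named list of numeric vectors (the axes), names among
#'   `alpha`, `delta`, `C0`, `C2`, `C3`, `C4`.
#' @param state Named vector `c(q =, qdot =, t =)` at which the charge is
#'   evaluated.
#' @param normalise Scale values to max |value| = 1.
#' @return A data frame: one column per grid axis plus a column `N`.
#' @export
noether_parameter_map <- function(family_template, grid,
                                  state = c(q = 1, qdot = 0, t = 1),
                                  normalise = FALSE) {
  allowed <- c("alpha", "delta", "C0", "C2", "C3", "C4")
  if (is.null(names(grid)) || !all(names(grid) %in% allowed))
    stop("grid axes must be named among ", paste(allowed, collapse = ", "))
  nodes <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  base <- list(alpha = family_template$alpha,
               delta = family_template$delta,
               C0 = family_coeff(family_template, 0),
               C2 = family_coeff(family_template, 2),
               C3 = family_coeff(family_template, 3),
               C4 = family_coeff(family_template, 4))
  vals <- vapply(seq_len(nrow(nodes)), function(i) {
    pars <- utils::modifyList(base, as.list(nodes[i, , drop = FALSE]))
    fam <- power_series_family(alpha = pars$alpha, delta = pars$delta,
                               C0 = pars$C0, C2 = pars$C2, C3 = pars$C3,
                               C4 = pars$C4)
    tryCatch(noether_charge(fam, state[["q"]], state[["qdot"]],
                            state[["t"]]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (normalise) {
    mx <- max(abs(vals), na.rm = TRUE)
    if (mx > 0) vals <- vals / mx
  }
  nodes$N <- vals
  nodes
}

family_coeff <- function(family, y) {
  hit <- family$terms$y == y & family$terms$z == 0
  if (any(hit)) sum(family$terms$coeff[hit]) else 0
}
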