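# The microscopic speed model: contact friction in the denominator,
# pheromone speed-up as a multiplicative factor, and the flow it predicts.

#' Pheromone speed factor
#'
#' The density-dependent multiplier on speed attributed to trail marking:
#' `alpha + beta * k * exp(-gamma * k)`.  It equals `alpha` on an unmarked
#' trail (k = 0), rises with density while marking intensifies, peaks at
#' exactly `k = 1/gamma`, and relaxes back to `alpha` at high density.
#'
#' @param k density in ants cm^-2 (vectorised).
#' @param params a [micro_params()] object.
#' @return Dimensionless speed multiplier.
#' @export
pheromone_factor <- function(k, params = micro_params()) {
  params$alpha + params$beta * k * exp(-params$gamma * k)
}

#' Density-dependent individual speed
#'
#' Combines the two opposing effects of crowding on an ant's speed.  Contacts
#' slow ants down: at density `k` an ant experiences on average `C(k) = c * k`
#' contacts while crossing the monitored section, each costing `dT` seconds,
#' so the expected crossing time is `T0 + dT * c * k`.  Trail pheromone
#' speeds them up by the factor [pheromone_factor()].  The resulting speed is
#'
#' `v(k) = L / (T0 + dT * c * k) * (alpha + beta * k * exp(-gamma * k))`
#'
#' which equals `L * alpha / T0` at zero density and stays positive for all
#' densities.
#'
#' @inheritParams pheromone_factor
#' @return Speed in cm s^-1.
#' @examples
#' speed_model(0)   # L * alpha / T0 = 2 * 0.812 / 0.95
#' @export
speed_model <- function(k, params = micro_params()) {
  if (any(k < 0)) ant_config_error("speed_model: density k must be >= 0")
  params$L / (params$T0 + params$dT * params$c * k) * pheromone_factor(k, params)
}

#' Predicted per-width flow from the speed model
#'
#' `q(k) = k * v(k)` with `v` from [speed_model()].  The flow rises roughly
#' linearly at low density (the pheromone speed-up offsets contact friction),
#' then plateaus: contact friction makes speed decay like `1/k`, which the
#' growing density exactly compensates.
#'
#' @inheritParams pheromone_factor
#' @return Flow in ants cm^-1 s^-1.
#' @seealso [limit_flow()] for the high-density limit.
#' @export
predict_flow <- function(k, params = micro_params()) {
  k * speed_model(k, params)
}

#' High-density limit of the predicted flow
#'
#' As density grows, `q(k) = k * v(k)` tends to the closed-form limit
#' `L * alpha / (dT * c)`: the pheromone bump dies off, and the `1/k` speed
#' decay from contact friction cancels against the density factor.  With the
#' default parameters the limit is 11.09 ants cm^-1 s^-1, slightly above the
#' observed plateau of about 10.
#'
#' @param params a [micro_params()] object.
#' @return Limiting flow in ants cm^-1 s^-1.
#' @examples
#' limit_flow()   # 11.09
#' @export
limit_flow <- function(params = micro_params()) {
  params$L * params$alpha / (params$dT * params$c)
}

#' Fit the pheromone speed model to tracked-ant records
#'
#' Estimates the three pheromone parameters (`alpha`, `beta`, `gamma`) of the
#' speed model by nonlinear least squares (Levenberg-Marquardt), holding the
#' mechanical constants `L`, `T0`, `dT` and the contact-rate slope `c` fixed.
#' The objective is evaluated on the travel-time scale: observed crossing
#' times `T` are fitted against `(T0 + dT * c * k) / (alpha + beta * k *
#' exp(-gamma * k))`.  Measured times carry additive noise, so least squares
#' on `T` is unbiased, whereas regressing reciprocal speeds `L/T` would
#' inherit a Jensen bias from the same noise; the two parameterisations are
#' identical at the optimum of the noiseless problem.
#'
#' U-turn records are excluded.  Records must span densities up to at least
#' 10 ants cm^-2, and must include spread in `k`; otherwise `beta` and
#' `gamma` are not identifiable and an error is raised.
#'
#' @param tracked data frame of tracked-ant records with columns `k_local`
#'   and `T` (and optionally `uturn`), e.g. from [generate_tracked()].
#' @param fixed a [micro_params()] object supplying `L`, `T0`, `dT`, `c`
#'   (its `alpha`, `beta`, `gamma` entries are ignored as starting values
#'   are fixed at 1, 0.1, 0.1).
#' @return Object of class `speed_fit`: list with `estimates`, `se`,
#'   `params` (a full `micro_params` with the fitted values substituted),
#'   `sse`, `n`.  Supports `coef`, `print` and `predict` (returning speeds).
#' @export
fit_speed_model <- function(tracked, fixed = micro_params()) {
  tracked <- drop_uturns(tracked)
  need_cols(tracked, c("k_local", "T"), "fit_speed_model")
  k <- tracked$k_local; Tobs <- tracked$T
  keep <- is.finite(k) & is.finite(Tobs)
  k <- k[keep]; Tobs <- Tobs[keep]
  if (length(k) < 30)
    ant_data_error("fit_speed_model: need at least 30 usable records")
  if (max(k) < 10 || stats::sd(k) == 0)
    ant_data_error(
      "fit_speed_model: records must span densities up to >= 10 ants cm^-2")
  denom <- fixed$T0 + fixed$dT * fixed$c * k
  resid_fn <- function(par)
    Tobs - denom / (par[1] + par[2] * k * exp(-par[3] * k))
  out <- tryCatch(
    minpack.lm::nls.lm(par = c(alpha = 1, beta = 0.1, gamma = 0.1),
                       lower = rep(1e-6, 3), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(out, "error") || !(out$info %in% 1:4))
    ant_fit_error("fit_speed_model: nonlinear fit did not converge")
  est <- out$par
  names(est) <- c("alpha", "beta", "gamma")
  sm <- summary(out)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(est)
  fitted_params <- micro_params(L = fixed$L, T0 = fixed$T0, dT = fixed$dT,
                                c = fixed$c, alpha = est[["alpha"]],
                                beta = est[["beta"]], gamma = est[["gamma"]])
  structure(list(estimates = est, se = se, params = fitted_params,
                 sse = sum(resid_fn(est)^2), n = length(k)),
            class = "speed_fit")
}

#' @export
coef.speed_fit <- function(object, ...) object$estimates

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("Pheromone speed-model fit (n = %d)\n", x$n))
  print(round(rbind(estimate = x$estimates, se = x$se), 4))
  cat(sprintf("SSE = %.4g;  implied limit flow = %.2f ants cm^-1 s^-1\n",
              x$sse, limit_flow(x$params)))
  invisible(x)
}

#' @export
predict.speed_fit <- function(object, k, ...) speed_model(k, object$params)
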