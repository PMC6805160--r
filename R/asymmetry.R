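# Directional asymmetry of the flow and the quadratic response surface of
# flow on density and asymmetry.

#' Per-second flow asymmetry
#'
#' The outbound fraction of the flow, `a = n_out / (n_out + n_in)`, computed
#' per second: 1 or 0 means unidirectional (asymmetric) traffic, 0.5 fully
#' bidirectional.  Seconds with zero total flow carry no direction
#' information and yield `NA`.
#'
#' @param obs data frame of flow/density records with columns `k`, `q`,
#'   `n_out`, `n_in`.
#' @return Data frame with columns `k`, `q`, `a`.
#' @export
asymmetry_series <- function(obs) {
  need_cols(obs, c("k", "q", "n_out", "n_in"), "asymmetry_series")
  tot <- obs$n_out + obs$n_in
  a <- ifelse(tot > 0, obs$n_out / tot, NA_real_)
  data.frame(k = obs$k, q = obs$q, a = a)
}

#' Quadratic response surface of flow on density and asymmetry
#'
#' Regresses per-second flow on density and flow asymmetry with standardized
#' coefficients, quantifying how much of the flow is explained by crowding
#' versus by the directional composition of the traffic.  Density `k`, the
#' outbound fraction `a` and the response `q` are each centred and scaled to
#' unit SD; the squares and the interaction are then formed from the scaled
#' predictors, and `q` is regressed on the five terms `z_k`, `z_k^2`, `z_a`,
#' `z_a^2`, `z_k z_a` by ordinary least squares.  Near-zero asymmetry terms
#' mean the flow isoclines run parallel to the asymmetry axis: flow depends
#' on density alone.
#'
#' @param records data frame from [asymmetry_series()] (columns `k`, `q`,
#'   `a`); rows with missing `a` are dropped.
#' @return Object of class `asym_surface`: list with `beta` (standardized
#'   coefficients named `density`, `density2`, `asymmetry`, `asymmetry2`,
#'   `density_x_asymmetry`), `r_squared`, `n` and the `lm` fit.
#' @examples
#' obs <- generate_macroscopic(generator_config(
#'   seed = 1, density_profile = "uniform", asym_profile = "constant"))
#' response_surface(asymmetry_series(obs))
#' @export
response_surface <- function(records) {
  need_cols(records, c("k", "q", "a"), "response_surface")
  d <- records[stats::complete.cases(records[c("k", "q", "a")]), ]
  if (nrow(d) < 100)
    ant_data_error(sprintf(
      "response_surface: need at least 100 complete records, got %d", nrow(d)))
  if (stats::sd(d$k) == 0 || stats::sd(d$a) == 0 || stats::sd(d$q) == 0)
    ant_data_error(
      "response_surface: no variation in density, asymmetry or flow")
  zk <- as.numeric(scale(d$k)); za <- as.numeric(scale(d$a))
  zq <- as.numeric(scale(d$q))
  X <- data.frame(zq = zq, zk = zk, zk2 = zk^2, za = za, za2 = za^2,
                  zka = zk * za)
  fit <- stats::lm(zq ~ zk + zk2 + za + za2 + zka, data = X)
  if (anyNA(stats::coef(fit)))
    ant_data_error("response_surface: collinear design; coefficients dropped")
  beta <- stats::coef(fit)[-1]
  names(beta) <- c("density", "density2", "asymmetry", "asymmetry2",
                   "density_x_asymmetry")
  structure(list(beta = beta, r_squared = summary(fit)$r.squared,
                 n = nrow(d), fit = fit),
            class = "asym_surface")
}

#' @export
coef.asym_surface <- function(object, ...) object$beta

#' @export
print.asym_surface <- function(x, ...) {
  cat(sprintf("Flow ~ density/asymmetry response surface (n = %d, R^2 = %.2f)\n",
              x$n, x$r_squared))
  print(round(x$beta, 3))
  invisible(x)
}
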