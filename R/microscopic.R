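# Individual-level regressions: contacts vs density, travel time vs
# contacts, free-flow speed, and travel-time curves stratified by contacts.

need_cols <- function(df, cols, where) {
  if (!is.data.frame(df))
    ant_data_error(sprintf("%s: expected a data frame of records", where))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ant_data_error(sprintf("%s: missing column(s) %s", where,
                           paste(miss, collapse = ", ")))
  invisible(df)
}

# U-turning ants are excluded from every regression: they contribute to
# density on the trail but never complete a crossing.
drop_uturns <- function(tracked) {
  if (is.data.frame(tracked) && "uturn" %in% names(tracked))
    tracked[!tracked$uturn, , drop = FALSE]
  else tracked
}

#' Contact rate against density
#'
#' Regression of the per-crossing contact count `C` on the local density `k`
#' through the origin (zero density forces zero contacts): `C = c * k`.
#' Returns the slope in contacts per (ant cm^-2) with its standard error and
#' the R-squared of the through-origin fit.
#'
#' @param tracked data frame of tracked-ant records with columns `k_local`
#'   and `C` (and optionally `uturn`; U-turn records are dropped).
#' @return Object of class `contact_fit`: list with `slope`, `se`,
#'   `r_squared`, `n` and the underlying `lm` fit.  `coef` returns the slope.
#' @examples
#' tr <- generate_tracked(2000, params = micro_params(),
#'                        config = generator_config(seed = 1))
#' fit_contact_rate(tr)
#' @export
fit_contact_rate <- function(tracked) {
  tracked <- drop_uturns(tracked)
  need_cols(tracked, c("k_local", "C"), "fit_contact_rate")
  d <- tracked[is.finite(tracked$k_local) & is.finite(tracked$C), ]
  if (nrow(d) < 30)
    ant_data_error("fit_contact_rate: need at least 30 usable records")
  if (all(d$k_local == 0))
    ant_data_error("fit_contact_rate: all densities are zero (slope undefined)")
  fit <- stats::lm(C ~ k_local - 1, data = d)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[1]),
                 se = sm$coefficients[1, "Std. Error"],
                 r_squared = sm$r.squared, n = nrow(d), fit = fit),
            class = "contact_fit")
}

#' @export
coef.contact_fit <- function(object, ...) c(c = object$slope)

#' @export
print.contact_fit <- function(x, ...) {
  cat(sprintf(
    "Contact rate: C = %.3f * k  (SE %.4f, R^2 = %.2f, n = %d)\n",
    x$slope, x$se, x$r_squared, x$n))
  invisible(x)
}

#' Travel time against contact count
#'
#' Ordinary least squares of the crossing time `T` on the contact count `C`:
#' `T = T0 + dT * C`.  The intercept is the free travel time (crossing
#' without contacts) and the slope is the time lost per contact.
#'
#' @inheritParams fit_contact_rate
#' @param tracked data frame with columns `C` and `T` (optionally `uturn`).
#' @return Object of class `travel_fit`: list with `T0`, `dT`, their
#'   standard errors (`se`, named), `r_squared`, `n` and the `lm` fit.
#'   `coef` returns `c(T0, dT)`.
#' @export
fit_travel_time <- function(tracked) {
  tracked <- drop_uturns(tracked)
  need_cols(tracked, c("C", "T"), "fit_travel_time")
  d <- tracked[is.finite(tracked$C) & is.finite(tracked$T), ]
  if (nrow(d) < 30)
    ant_data_error("fit_travel_time: need at least 30 usable records")
  if (stats::sd(d$C) == 0)
    ant_data_error(
      "fit_travel_time: contact count is constant; slope unidentifiable")
  fit <- stats::lm(T ~ C, data = d)
  sm <- summary(fit)
  est <- stats::coef(fit)
  structure(list(T0 = unname(est[1]), dT = unname(est[2]),
                 se = c(T0 = sm$coefficients[1, "Std. Error"],
                        dT = sm$coefficients[2, "Std. Error"]),
                 r_squared = sm$r.squared, n = nrow(d), fit = fit),
            class = "travel_fit")
}

#' @export
coef.travel_fit <- function(object, ...) c(T0 = object$T0, dT = object$dT)

#' @export
print.travel_fit <- function(x, ...) {
  cat(sprintf(
    "Travel time: T = %.3f + %.3f * C  (SEs %.4f / %.4f, R^2 = %.2f, n = %d)\n",
    x$T0, x$dT, x$se[["T0"]], x$se[["dT"]], x$r_squared, x$n))
  invisible(x)
}

#' Free-flow speed of individual crossings
#'
#' Removes the time spent in contacts from an observed crossing and converts
#' the remainder to a speed: `v_f = L / (T - C * dT)`.  Records whose
#' contact-corrected time is not positive cannot yield a speed; they come
#' back as `NA` and their count is attached as the `n_invalid` attribute.
#'
#' @param T crossing time in seconds (vectorised).
#' @param C contact count (vectorised).
#' @param dT time lost per contact in seconds.
#' @param L length of the monitored section in cm.
#' @return Speeds in cm s^-1, `NA` where invalid, with attribute
#'   `n_invalid`.
#' @examples
#' free_flow_speed(T = 1.43, C = 2)   # same ant speed as a contact-free 0.95 s crossing
#' @export
free_flow_speed <- function(T, C, dT = 0.24, L = 2) {
  if (dT <= 0 || L <= 0)
    ant_config_error("free_flow_speed: dT and L must be positive")
  t0 <- T - C * dT
  bad <- !is.finite(t0) | t0 <= 0
  v <- ifelse(bad, NA_real_, L / t0)
  attr(v, "n_invalid") <- sum(bad)
  v
}

#' Smoothed travel-time curves by contact stratum
#'
#' For each requested contact count, fits a local polynomial regression
#' (degree 2, tricube weights — `stats::loess`) of travel time on density
#' within the stratum of records having exactly that many contacts, and
#' evaluates the smooth on a common density grid.  Strata with fewer than
#' `min_n` records are skipped with a warning.  The curves visualise the
#' pheromone effect: for a fixed number of contacts, crossing times dip at
#' intermediate densities.
#'
#' @param tracked data frame with columns `k_local`, `C`, `T` (optionally
#'   `uturn`).
#' @param contact_levels integer contact counts to stratify on.
#' @param span loess span (fraction of records entering each local fit).
#' @param grid_n number of grid points spanning the stratum's density range.
#' @param min_n minimum records per stratum.
#' @return Data frame with columns `C` (stratum), `k` (grid) and `T_fit`.
#' @export
travel_time_curves <- function(tracked, contact_levels = 0:4, span = 0.75,
                               grid_n = 50, min_n = 30) {
  tracked <- drop_uturns(tracked)
  need_cols(tracked, c("k_local", "C", "T"), "travel_time_curves")
  out <- list()
  for (lev in contact_levels) {
    d <- tracked[tracked$C == lev, ]
    if (nrow(d) < min_n) {
      warning(sprintf(
        "travel_time_curves: stratum C = %d has %d < %d records; skipped",
        lev, nrow(d), min_n))
      next
    }
    kg <- seq(min(d$k_local), max(d$k_local), length.out = grid_n)
    lo <- stats::loess(T ~ k_local, data = d, degree = 2, span = span,
                       family = "gaussian",
                       control = stats::loess.control(surface = "direct"))
    out[[as.character(lev)]] <- data.frame(
      C = lev, k = kg, T_fit = stats::predict(lo, newdata = data.frame(k_local = kg)))
  }
  if (!length(out))
    ant_data_error("travel_time_curves: no stratum had enough records")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
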