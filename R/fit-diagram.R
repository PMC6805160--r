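# Nonlinear least-squares fitting of flow-density diagrams and
# Akaike-weight model selection.

#' Fit a fundamental diagram to flow/density observations
#'
#' Estimates the parameters of one flow-density model by least squares on the
#' per-second `(k, q)` pairs.  The three smooth models (Greenshields,
#' Pipes-Munjal, Underwood) are fitted with the Levenberg-Marquardt
#' algorithm, restarting from perturbed initial values on failure.  The
#' two-phase piecewise-linear model is non-smooth at its breakpoint, so it is
#' fitted by profiling the residual sum of squares over a grid of candidate
#' breakpoints (step 0.1 ants cm^-2) with the slope solved in closed form at
#' each candidate, followed by a continuous golden-section refinement around
#' the best grid point.
#'
#' @param obs a data frame of flow/density observations with numeric columns
#'   `k` (density, ants cm^-2) and `q` (per-width flow, ants cm^-1 s^-1),
#'   e.g. from [generate_macroscopic()] or [read_flow_density()].
#' @param model an [fd_model()] or its name.
#' @param init `"auto"` (data-driven starting values) or a named numeric
#'   vector matching the model's parameter names.
#' @return An object of class `fd_fit` with components `model`, `estimates`,
#'   `se`, `sse`, `n`, `aic` and (once [akaike_weights()] has been applied)
#'   `akaike_weight`.  Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot`.
#' @examples
#' cfg <- generator_config(seed = 1, duration = 600)
#' obs <- generate_macroscopic(cfg, micro_params())
#' fit <- fit_diagram(obs, "two_phase")
#' coef(fit)
#' @export
fit_diagram <- function(obs, model, init = "auto") {
  if (is.character(model)) model <- fd_model(model)
  if (!inherits(model, "fd_model"))
    ant_config_error("fit_diagram: 'model' must be an fd_model or its name")
  if (!is.data.frame(obs) || !all(c("k", "q") %in% names(obs)))
    ant_data_error("fit_diagram: 'obs' must contain columns 'k' and 'q'")
  k <- as.numeric(obs$k); q <- as.numeric(obs$q)
  keep <- is.finite(k) & is.finite(q)
  k <- k[keep]; q <- q[keep]
  n <- length(k)
  if (n < 10)
    ant_data_error(sprintf(
      "fit_diagram: need at least 10 observations, got %d", n))
  if (stats::sd(k) == 0)
    ant_data_error("fit_diagram: no spread in density k")
  if (all(q == 0))
    ant_data_error("fit_diagram: all flows are zero (degenerate data)")

  start <- if (identical(init, "auto")) fd_auto_init(model, k, q) else {
    if (!is.numeric(init) || !all(model$par_names %in% names(init)))
      ant_config_error(sprintf(
        "fit_diagram: init must name parameters %s",
        paste(model$par_names, collapse = ", ")))
    init[model$par_names]
  }

  res <- if (model$name == "two_phase") fd_fit_two_phase(k, q) else
    fd_fit_lm(model, k, q, start)

  p <- length(model$par_names)
  aic <- n * log(res$sse / n) + 2 * (p + 1)
  structure(list(
    model = model, estimates = res$par, se = res$se, sse = res$sse,
    n = n, aic = aic, akaike_weight = NA_real_,
    data = data.frame(k = k, q = q)
  ), class = "fd_fit")
}

# Data-driven starting values: free slope from the lowest-density decile,
# breakpoint/jam density from the observed density range.
fd_auto_init <- function(model, k, q) {
  pos <- k > 0
  kd <- k[pos]; qd <- q[pos]
  cut <- stats::quantile(kd, 0.1)
  low <- kd <= cut
  v0 <- stats::median(qd[low] / kd[low])
  if (!is.finite(v0) || v0 <= 0) v0 <- max(q) / max(k)
  switch(model$name,
    greenshields = c(v_f = v0, k_j = 1.2 * max(k)),
    pipes_munjal = c(v_f = v0, k_j = 1.2 * max(k), p = 2),
    underwood    = c(v_f = v0, k_m = stats::median(kd)),
    two_phase    = c(v = v0, k_j = stats::median(kd)))
}

# Levenberg-Marquardt fit for the smooth models, with perturbed restarts.
fd_fit_lm <- function(model, k, q, start) {
  resid_fn <- function(par) {
    names(par) <- model$par_names
    q - model$flow(k, par)
  }
  lower <- rep(1e-8, length(start))
  tries <- list(start, start * 0.5, start * 2, start * c(1, 0.5, 2)[
    seq_along(start)])
  last_err <- NULL
  for (st in tries) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(out, "error") && out$info %in% 1:4) {
      par <- out$par; names(par) <- model$par_names
      sse <- sum(resid_fn(par)^2)
      se <- fd_se(function(pp) model$flow(k, pp), par, sse, length(k))
      return(list(par = par, se = se, sse = sse))
    }
    last_err <- out
  }
  ant_fit_error(sprintf(
    "fit_diagram: %s fit did not converge after restarts (%s)",
    model$name,
    if (inherits(last_err, "error")) conditionMessage(last_err)
    else paste("nls.lm info", last_err$info)))
}

# Two-phase fit: profile SSE over a breakpoint grid with the slope in closed
# form, then refine the breakpoint continuously.
fd_fit_two_phase <- function(k, q) {
  prof <- function(kj) {
    m <- pmin(k, kj)
    v <- sum(q * m) / sum(m * m)
    c(v = v, sse = sum((q - v * m)^2))
  }
  grid <- seq(0.1, max(k), by = 0.1)
  sses <- vapply(grid, function(kj) prof(kj)["sse"], numeric(1))
  kj0 <- grid[which.min(sses)]
  opt <- stats::optimize(function(kj) prof(kj)["sse"],
                         interval = c(max(0.05, kj0 - 0.1),
                                      min(max(k), kj0 + 0.1)),
                         tol = 1e-9)
  kj <- opt$minimum
  pr <- prof(kj)
  par <- c(v = unname(pr["v"]), k_j = kj)
  flow <- function(pp) two_phase_flow(k, pp[["v"]], pp[["k_j"]])
  se <- fd_se(flow, par, pr[["sse"]], length(k))
  list(par = par, se = se, sse = pr[["sse"]])
}

# Gaussian standard errors from a numerical Jacobian of the flow function.
fd_se <- function(flow_par, par, sse, n) {
  p <- length(par)
  J <- matrix(0, n, p)
  h <- pmax(abs(par), 1) * 1e-6
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    J[, j] <- (flow_par(up) - flow_par(dn)) / (2 * h[j])
  }
  sigma2 <- sse / max(n - p, 1)
  V <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, p) else sqrt(pmax(diag(V), 0))
  names(se) <- names(par)
  se
}

#' @export
coef.fd_fit <- function(object, ...) object$estimates

#' @export
fitted.fd_fit <- function(object, ...)
  object$model$flow(object$data$k, object$estimates)

#' @export
residuals.fd_fit <- function(object, ...) object$data$q - fitted(object)

#' Predict flow from a fitted fundamental diagram
#'
#' @param object an `fd_fit`.
#' @param newdata optional data frame with a `k` column, or a numeric density
#'   vector via `k`; defaults to the fitted densities.
#' @param k numeric density vector (alternative to `newdata`).
#' @param ... unused.
#' @return Predicted per-width flow at the requested densities.
#' @export
predict.fd_fit <- function(object, newdata = NULL, k = NULL, ...) {
  kk <- if (!is.null(k)) k else if (!is.null(newdata)) newdata$k
        else object$data$k
  object$model$flow(kk, object$estimates)
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("Fundamental diagram fit: %s (n = %d)\n", x$model$name, x$n))
  est <- rbind(estimate = x$estimates, se = x$se)
  print(round(est, 4))
  cat(sprintf("SSE = %.4g, AIC = %.2f", x$sse, x$aic))
  if (!is.na(x$akaike_weight))
    cat(sprintf(", Akaike weight = %.3f", x$akaike_weight))
  cat("\n")
  invisible(x)
}

#' @export
summary.fd_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Residual SD = %.4g\n",
              sqrt(object$sse / max(object$n - length(object$estimates), 1))))
  invisible(object)
}

#' @export
plot.fd_fit <- function(x, bin_width = 0.5, ...) {
  bs <- bin_summary(x$data, bin_width)
  kk <- seq(0, max(x$data$k), length.out = 200)
  plot(bs$k_mid, bs$q_mean, xlab = "density k (ants cm^-2)",
       ylab = "flow q (ants cm^-1 s^-1)",
       main = sprintf("%s fit", x$model$name), pch = 19, ...)
  graphics::arrows(bs$k_mid, bs$q_mean - bs$q_sd, bs$k_mid,
                   bs$q_mean + bs$q_sd, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  graphics::lines(kk, x$model$flow(kk, x$estimates), col = "red3", lwd = 2)
  invisible(x)
}

#' Akaike weights across a set of diagram fits
#'
#' Computes, for fits of competing flow-density models to the same
#' observations, the least-squares AIC `n * log(SSE/n) + 2 * (p + 1)` (the
#' `+1` counts the error variance) and the Akaike weights
#' `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)` with `D_i = AIC_i - min(AIC)`.
#' The weight is the conditional probability of the model within the
#' compared set.
#'
#' @param fits a list of [fd_fit] objects fitted to the same observation set.
#' @return The list with each fit's `akaike_weight` filled in, classed
#'   `fd_selection`; printing shows the model-selection table.
#' @examples
#' cfg <- generator_config(seed = 1, duration = 600)
#' obs <- generate_macroscopic(cfg, micro_params())
#' fits <- lapply(c("two_phase", "greenshields"), fit_diagram, obs = obs)
#' akaike_weights(fits)
#' @export
akaike_weights <- function(fits) {
  if (!is.list(fits) || length(fits) == 0 ||
      !all(vapply(fits, inherits, logical(1), "fd_fit")))
    ant_config_error("akaike_weights: need a non-empty list of fd_fit objects")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    ant_data_error("akaike_weights: fits are not on the same observation set")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  d <- aic - min(aic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  for (i in seq_along(fits)) fits[[i]]$akaike_weight <- w[i]
  names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  structure(fits, class = "fd_selection")
}

#' @export
print.fd_selection <- function(x, ...) {
  cat("Fundamental-diagram model selection\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.fd_selection <- function(x, ...) {
  df <- data.frame(
    model = vapply(x, function(f) f$model$name, character(1)),
    n_par = vapply(x, function(f) length(f$estimates), integer(1)),
    sse = vapply(x, `[[`, numeric(1), "sse"),
    aic = vapply(x, `[[`, numeric(1), "aic"),
    akaike_weight = vapply(x, `[[`, numeric(1), "akaike_weight"))
  df[order(-df$akaike_weight), ]
}

#' Binned mean and spread of flow against density
#'
#' Summarises flow over half-open density bins `[lo, lo + bin_width)`,
#' reporting the per-bin count, mean and standard deviation of `q`.  Empty
#' bins are omitted and the SD of a single-observation bin is `NA` (the
#' unbiased SD is undefined at n = 1).
#'
#' @param obs data frame with columns `k` and `q`.
#' @param bin_width bin width in density units (ants cm^-2).
#' @return Data frame with columns `k_lo`, `k_mid`, `n`, `q_mean`, `q_sd`.
#' @export
bin_summary <- function(obs, bin_width = 0.5) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    ant_config_error("bin_summary: bin_width must be positive")
  k <- obs$k; q <- obs$q
  idx <- floor(k / bin_width)
  grp <- sort(unique(idx))
  out <- do.call(rbind, lapply(grp, function(g) {
    qi <- q[idx == g]
    data.frame(k_lo = g * bin_width, k_mid = (g + 0.5) * bin_width,
               n = length(qi), q_mean = mean(qi),
               q_sd = if (length(qi) > 1) stats::sd(qi) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
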