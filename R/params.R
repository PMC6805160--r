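#' Microscopic traffic parameters
#'
#' Bundles the constants of the individual-level traffic model: the length of
#' the monitored trail section, the free travel time, the time lost per
#' contact, the contact-rate slope, and the three pheromone-effect parameters.
#' Defaults are the values estimated for Argentine ants on a 2 cm bridge
#' section: crossing an empty section takes `T0` = 0.95 s, each physical
#' contact costs `dT` = 0.24 s, contacts accrue at `c` = 0.61 per unit density
#' (ants cm^-2), and the trail-marking (pheromone) effect multiplies speed by
#' `alpha + beta * k * exp(-gamma * k)`.
#'
#' @param L length of the monitored section in cm.
#' @param T0 free travel time in seconds (no contacts, unmarked trail factor
#'   excluded).
#' @param dT time lost per contact, in seconds.
#' @param c contact-rate slope, contacts per (ant cm^-2).
#' @param alpha intrinsic attractiveness of the unmarked trail
#'   (dimensionless speed multiplier at zero density).
#' @param beta strength of the density-dependent pheromone speed-up.
#' @param gamma inverse density scale of the pheromone effect; the speed
#'   multiplier peaks at density `1/gamma`.
#'
#' @return An object of class `micro_params`: a named list of the seven
#'   constants.
#' @seealso [speed_model()], [predict_flow()], [limit_flow()]
#' @examples
#' p <- micro_params()
#' limit_flow(p)
#' @export
micro_params <- function(L = 2, T0 = 0.95, dT = 0.24, c = 0.61,
                         alpha = 0.812, beta = 0.160, gamma = 0.156) {
  p <- list(L = L, T0 = T0, dT = dT, c = c,
            alpha = alpha, beta = beta, gamma = gamma)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    ant_config_error(sprintf(
      "micro_params: all parameters must be single positive numbers (bad: %s)",
      paste(names(p)[bad], collapse = ", ")))
  structure(p, class = "micro_params")
}

#' @export
print.micro_params <- function(x, ...) {
  cat("Microscopic traffic parameters\n")
  cat(sprintf("  section length L: %g cm\n", x$L))
  cat(sprintf("  free travel time T0: %g s;  delay per contact dT: %g s\n",
              x$T0, x$dT))
  cat(sprintf("  contact rate c: %g contacts per (ant cm^-2)\n", x$c))
  cat(sprintf("  pheromone factor: %g + %g k exp(-%g k)  (peak at k = %.2f)\n",
              x$alpha, x$beta, x$gamma, 1 / x$gamma))
  invisible(x)
}

#' Configuration for the synthetic traffic generator
#'
#' Collects everything the synthetic-data generator needs: trail geometry,
#' recording duration, the density trajectory, noise switches and the RNG
#' seed.  Defaults emulate a one-hour recording on a 1 cm wide bridge where
#' recruitment builds density up to its ceiling over the first ten minutes
#' and the flow direction drifts from all-outbound to balanced.
#'
#' @param bridge_width trail width in cm (the experiments used 0.5, 1 and
#'   2 cm).
#' @param duration recording length in seconds.
#' @param density_max density ceiling in ants cm^-2; observed densities never
#'   exceeded 18.
#' @param ramp_time seconds over which density builds up to the ceiling
#'   (logistic ramp centred at `ramp_time/2`); 0 gives a constant trajectory
#'   at `density_max`.
#' @param seed integer RNG seed, echoed into all generated output; `NULL`
#'   leaves the RNG state alone.
#' @param uturn_prob probability that a tracked ant makes a U-turn during a
#'   crossing.
#' @param count_noise logical; draw per-second directional counts from a
#'   Poisson distribution around the model mean (`FALSE` gives rounded
#'   means).
#' @param travel_noise_sd standard deviation, in seconds, of the additive
#'   truncated-normal noise on generated travel times (truncated below at
#'   `0.1 * T0`); 0 disables it.
#' @param density_jitter_sd relative standard deviation of the Gaussian
#'   jitter on the density trajectory (fraction of the current level,
#'   truncated to stay inside `[0, density_max]`); 0 disables it.
#' @param asym_profile outbound-fraction profile: `"logistic"` (drifts from 1
#'   to 0.5 on the same clock as the density ramp), `"constant"` (0.5
#'   throughout), or a function of the time vector returning values in
#'   `[0, 1]`.
#' @param density_profile density trajectory shape: `"logistic"` (ramp then
#'   plateau), `"uniform"` (i.i.d. uniform on `[0, density_max]`), a function
#'   of the time vector, or a numeric vector of length `duration`.
#'
#' @return An object of class `generator_config`.
#' @seealso [density_trajectory()], [generate_macroscopic()],
#'   [generate_tracked()]
#' @export
generator_config <- function(bridge_width = 1, duration = 3600,
                             density_max = 18, ramp_time = 600,
                             seed = NULL, uturn_prob = 0.01,
                             count_noise = TRUE, travel_noise_sd = 0.3,
                             density_jitter_sd = 0.05,
                             asym_profile = "logistic",
                             density_profile = "logistic") {
  stopifnot_config(is.numeric(bridge_width) && bridge_width > 0,
                   "bridge_width must be a positive length in cm")
  stopifnot_config(is.numeric(duration) && duration >= 1,
                   "duration must be a positive number of seconds")
  stopifnot_config(is.numeric(density_max) && density_max >= 0,
                   "density_max must be non-negative")
  stopifnot_config(is.numeric(ramp_time) && ramp_time >= 0,
                   "ramp_time must be non-negative")
  stopifnot_config(is.numeric(uturn_prob) && uturn_prob >= 0 && uturn_prob <= 1,
                   "uturn_prob must lie in [0, 1]")
  stopifnot_config(isTRUE(count_noise) || isFALSE(count_noise),
                   "count_noise must be TRUE or FALSE")
  stopifnot_config(is.numeric(travel_noise_sd) && travel_noise_sd >= 0,
                   "travel_noise_sd must be non-negative")
  stopifnot_config(is.numeric(density_jitter_sd) && density_jitter_sd >= 0,
                   "density_jitter_sd must be non-negative")
  ok_prof <- function(p, choices) (is.character(p) && p %in% choices) ||
    is.function(p) || is.numeric(p)
  stopifnot_config(ok_prof(asym_profile, c("logistic", "constant")),
                   "asym_profile must be 'logistic', 'constant', a function or numeric")
  stopifnot_config(ok_prof(density_profile, c("logistic", "uniform")),
                   "density_profile must be 'logistic', 'uniform', a function or numeric")
  structure(list(
    bridge_width = bridge_width, duration = as.integer(duration),
    density_max = density_max, ramp_time = ramp_time, seed = seed,
    uturn_prob = uturn_prob, count_noise = count_noise,
    travel_noise_sd = travel_noise_sd, density_jitter_sd = density_jitter_sd,
    asym_profile = asym_profile, density_profile = density_profile
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic traffic generator configuration\n")
  cat(sprintf("  bridge width %g cm, duration %d s, density ceiling %g ants cm^-2\n",
              x$bridge_width, x$duration, x$density_max))
  cat(sprintf("  ramp %g s; count noise %s; travel noise sd %g s; density jitter %g\n",
              x$ramp_time, if (x$count_noise) "on" else "off",
              x$travel_noise_sd, x$density_jitter_sd))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
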