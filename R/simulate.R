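# Seeded statistical generator for synthetic traffic data.  It reproduces
# the statistical structure the analysis assumes -- a recruitment-style
# density build-up, Poisson counting noise on per-second crossings, Poisson
# contacts linear in density, additive travel-time noise, rare U-turns --
# without simulating individual positions or pheromone fields.

# Density trajectory without touching the RNG seed (callers manage seeding).
density_traj_ <- function(config) {
  t <- seq_len(config$duration) - 1
  prof <- config$density_profile
  k <- if (is.numeric(prof)) {
    if (length(prof) != config$duration)
      ant_config_error(sprintf(
        "density_profile vector must have length %d", config$duration))
    prof
  } else if (is.function(prof)) {
    prof(t)
  } else if (prof == "uniform") {
    stats::runif(config$duration, 0, config$density_max)
  } else {                                        # logistic recruitment ramp
    if (config$ramp_time == 0) rep(config$density_max, config$duration)
    else config$density_max /
      (1 + exp(-(t - config$ramp_time / 2) / (config$ramp_time / 8)))
  }
  if (config$density_jitter_sd > 0 && !is.numeric(prof))
    k <- k + stats::rnorm(length(k), 0, config$density_jitter_sd * k)
  pmin(pmax(k, 0), config$density_max)
}

# Outbound fraction over time: outbound ants dominate before the first
# foragers return, then the flow balances.
asym_traj_ <- function(config) {
  t <- seq_len(config$duration) - 1
  prof <- config$asym_profile
  a <- if (is.numeric(prof)) rep_len(prof, config$duration)
  else if (is.function(prof)) prof(t)
  else if (prof == "constant") rep(0.5, config$duration)
  else if (config$ramp_time == 0) rep(0.5, config$duration)
  else 1 - 0.5 / (1 + exp(-(t - config$ramp_time / 2) / (config$ramp_time / 8)))
  if (any(a < 0 | a > 1))
    ant_config_error("asym_profile values must lie in [0, 1]")
  a
}

#' Synthetic density trajectory
#'
#' Generates one density value per second.  The default profile is a
#' logistic recruitment ramp `density_max / (1 + exp(-(t - ramp_time/2) /
#' (ramp_time/8)))` -- density builds up over the ramp and then sits at the
#' ceiling -- with optional multiplicative Gaussian jitter, truncated so
#' values stay inside `[0, density_max]`.
#'
#' @param config a [generator_config()]; its `seed` (if any) is applied
#'   before drawing jitter.
#' @return Numeric vector of length `config$duration`, densities in
#'   ants cm^-2.
#' @export
density_trajectory <- function(config) {
  if (!inherits(config, "generator_config"))
    ant_config_error("density_trajectory: 'config' must be a generator_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  density_traj_(config)
}

#' Generate synthetic per-second flow/density records
#'
#' Simulates a recording: each second carries a density from the trajectory,
#' an expected total crossing count `q(k) * width` with `q` from the
#' microscopic flow prediction [predict_flow()] (or any flow function you
#' supply), split into outbound and inbound according to the asymmetry
#' profile.  With `count_noise` on, the two directional counts are
#' independent Poisson draws around their means; off, they are rounded
#' means.  The recorded flow is `(n_out + n_in) / width` exactly.
#'
#' @param config a [generator_config()].
#' @param params a [micro_params()] used by the default flow function.
#' @param flow_fn optional function `k -> q` replacing the microscopic flow
#'   prediction as the generating mean (e.g. a two-phase curve
#'   `function(k) two_phase_flow(k, 1.25, 8)`).
#' @param experiment_id label stamped on every record.
#' @return Data frame with columns `t`, `k`, `n_out`, `n_in`, `width`, `q`,
#'   `experiment_id`; the seed used is attached as attribute `seed`.
#' @examples
#' obs <- generate_macroscopic(generator_config(seed = 1, duration = 300))
#' head(obs)
#' @export
generate_macroscopic <- function(config = generator_config(),
                                 params = micro_params(), flow_fn = NULL,
                                 experiment_id = "sim") {
  if (!inherits(config, "generator_config"))
    ant_config_error("generate_macroscopic: 'config' must be a generator_config")
  if (is.null(flow_fn)) flow_fn <- function(k) predict_flow(k, params)
  if (!is.function(flow_fn))
    ant_config_error("generate_macroscopic: 'flow_fn' must be a function of k")
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- density_traj_(config)
  a <- asym_traj_(config)
  mean_total <- flow_fn(k) * config$bridge_width
  if (config$count_noise) {
    n_out <- stats::rpois(length(k), mean_total * a)
    n_in  <- stats::rpois(length(k), mean_total * (1 - a))
  } else {
    n_tot <- round(mean_total)
    n_out <- round(n_tot * a)
    n_in  <- n_tot - n_out
  }
  out <- data.frame(
    t = seq_len(config$duration) - 1L, k = k,
    n_out = as.integer(n_out), n_in = as.integer(n_in),
    width = config$bridge_width,
    q = (n_out + n_in) / config$bridge_width,
    experiment_id = experiment_id)
  attr(out, "seed") <- config$seed
  out
}

#' Generate synthetic tracked-ant records
#'
#' Simulates individually tracked crossings of the monitored section.  For
#' each record the local density `k` comes from `k_sampler`; the contact
#' count is Poisson with mean `c * k`; the crossing time is
#' `(T0 + dT * C) / phf(k)` -- contacts add their delay, pheromone divides
#' the time by the speed factor -- plus additive truncated-normal noise (sd
#' `config$travel_noise_sd`, truncated below at `0.1 * T0`).  A U-turn flag
#' is drawn Bernoulli(`config$uturn_prob`); U-turners are retained in the
#' table but excluded from the fitting functions.
#'
#' @param n number of records.
#' @param k_sampler densities: `NULL` for the default uniform draw on
#'   `[0, 16]` ants cm^-2, a function of `n`, or a numeric vector (length
#'   `n`, or sampled from with replacement).
#' @param params a [micro_params()] giving the generating constants.
#' @param config a [generator_config()] (seed and noise settings).
#' @param pheromone logical; apply the pheromone speed factor (`FALSE`
#'   forces the factor to 1, leaving pure contact friction).
#' @return Data frame with columns `direction`, `k_local`, `C`, `T`,
#'   `uturn`; the seed used is attached as attribute `seed`.
#' @examples
#' tr <- generate_tracked(1000, config = generator_config(seed = 1))
#' fit_travel_time(tr)
#' @export
generate_tracked <- function(n, k_sampler = NULL, params = micro_params(),
                             config = generator_config(), pheromone = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    ant_config_error("generate_tracked: n must be a positive count")
  n <- as.integer(n)
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- if (is.null(k_sampler)) stats::runif(n, 0, 16)
  else if (is.function(k_sampler)) k_sampler(n)
  else if (is.numeric(k_sampler)) {
    if (length(k_sampler) == n) k_sampler
    else sample(k_sampler, n, replace = TRUE)
  } else ant_config_error(
    "generate_tracked: k_sampler must be NULL, a function or numeric")
  if (length(k) != n || any(!is.finite(k)) || any(k < 0))
    ant_config_error("generate_tracked: sampled densities must be n finite values >= 0")
  C <- stats::rpois(n, params$c * k)
  phf <- if (pheromone) pheromone_factor(k, params) else rep(1, n)
  Tm <- (params$T0 + params$dT * C) / phf
  T <- Tm
  if (config$travel_noise_sd > 0) {
    T <- Tm + stats::rnorm(n, 0, config$travel_noise_sd)
    lo <- 0.1 * params$T0
    while (any(bad <- T < lo))
      T[bad] <- Tm[bad] + stats::rnorm(sum(bad), 0, config$travel_noise_sd)
  }
  out <- data.frame(
    direction = sample(c("outbound", "inbound"), n, replace = TRUE),
    k_local = k, C = as.integer(C), T = T,
    uturn = stats::runif(n) < config$uturn_prob)
  attr(out, "seed") <- config$seed
  out
}
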