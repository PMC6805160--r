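# Shared fixtures: small noiseless observation tables built in code.

# Flow/density table with exact two-phase flow values.
two_phase_obs <- function(k = seq(0.5, 16, by = 0.5), v = 1.25, k_j = 8) {
  data.frame(k = k, q = two_phase_flow(k, v, k_j))
}

# Tracked records following the mean speed model exactly: average contacts
# c * k, no Poisson draw, no noise.
eq_speed_tracked <- function(k = seq(0, 16, length.out = 400),
                             p = micro_params()) {
  Tm <- (p$T0 + p$dT * p$c * k) / pheromone_factor(k, p)
  data.frame(direction = "outbound", k_local = k,
             C = p$c * k, T = Tm, uturn = FALSE)
}

default_planted <- c(c = 0.61, T0 = 0.95, dT = 0.24,
                     alpha = 0.812, beta = 0.160, gamma = 0.156)
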