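test_that("density trajectory respects its ramp, bounds and degenerate cases", {
  cfg <- generator_config(ramp_time = 0, density_max = 5, duration = 100,
                          density_jitter_sd = 0)
  expect_equal(density_trajectory(cfg), rep(5, 100))
  cfg0 <- generator_config(density_max = 0, duration = 50, seed = 1)
  expect_equal(density_trajectory(cfg0), rep(0, 50))
  # recruitment ramp reaches the ceiling: final-quarter mean within 5%
  cfg1 <- generator_config(density_jitter_sd = 0)
  k <- density_trajectory(cfg1)
  expect_length(k, 3600)
  last_q <- k[2701:3600]
  expect_gt(mean(last_q) / cfg1$density_max, 0.95)
  # jittered trajectories stay inside [0, density_max]
  for (s in 1:5) {
    kj <- density_trajectory(generator_config(seed = s))
    expect_true(all(kj >= 0 & kj <= 18))
  }
  expect_error(generator_config(duration = 0), class = "ant_config_error")
})

test_that("macroscopic generator reproduces the mean flow with noise off", {
  dur <- 200
  cfg <- generator_config(duration = dur, count_noise = FALSE,
                          density_jitter_sd = 0, asym_profile = "constant",
                          density_profile = rep(4, dur), bridge_width = 1)
  obs <- generate_macroscopic(cfg)
  q4 <- predict_flow(4)
  expect_true(all(obs$q == round(q4 * cfg$bridge_width) / cfg$bridge_width))
  expect_true(all(abs(obs$q - q4) <= 0.5 / cfg$bridge_width))
  # zero density -> zero counts
  cfg0 <- generator_config(duration = 50, density_max = 0, seed = 2)
  obs0 <- generate_macroscopic(cfg0)
  expect_true(all(obs0$n_out == 0 & obs0$n_in == 0 & obs0$q == 0))
})

test_that("generator output is reproducible per seed and self-consistent", {
  cfg <- generator_config(seed = 21, duration = 600)
  a <- generate_macroscopic(cfg)
  b <- generate_macroscopic(cfg)
  expect_identical(a, b)
  c2 <- generate_macroscopic(generator_config(seed = 22, duration = 600))
  expect_false(identical(a, c2))
  # flow and counts agree exactly: q = (n_out + n_in) / width
  expect_equal(a$q, (a$n_out + a$n_in) / a$width)
  expect_equal(sum(a$n_out + a$n_in), sum(a$q * a$width))
  # densities never exceed the ceiling; occupancy stays below 0.8
  expect_true(all(a$k <= 18))
  expect_true(all(occupancy(a$k, 4.4) <= 0.8))
  tr1 <- generate_tracked(500, config = generator_config(seed = 5))
  tr2 <- generate_tracked(500, config = generator_config(seed = 5))
  expect_identical(tr1, tr2)
})

test_that("tracked records follow the contact/travel-time mean structure", {
  p <- micro_params()
  cfg <- generator_config(seed = 9, travel_noise_sd = 0, uturn_prob = 0)
  # noise off, pheromone factor off: T = T0 + dT * C exactly
  tr <- generate_tracked(500, config = cfg, pheromone = FALSE)
  expect_equal(tr$T, p$T0 + p$dT * tr$C)
  expect_false(any(tr$uturn))
  # regressing generated T on C returns the planted line exactly
  tt <- suppressWarnings(fit_travel_time(tr))
  expect_equal(coef(tt), c(T0 = 0.95, dT = 0.24), tolerance = 1e-9)
  # Poisson contacts: sample mean of C at k = 10 within 3 SE of 6.1
  trk <- generate_tracked(1e4, k_sampler = function(n) rep(10, n),
                          config = generator_config(seed = 10))
  se <- sd(trk$C) / sqrt(nrow(trk))
  expect_lt(abs(mean(trk$C) - 6.1), 3 * se)
  # U-turn flag frequency matches its probability
  tru <- generate_tracked(2e4, config = generator_config(seed = 12))
  expect_lt(abs(mean(tru$uturn) - 0.01), 3 * sqrt(0.01 * 0.99 / 2e4))
  expect_error(generate_tracked(0), class = "ant_config_error")
  expect_error(generate_tracked(10, k_sampler = "bad"),
               class = "ant_config_error")
})
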