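test_that("contact-rate regression recovers exact and planted slopes", {
  k <- seq(0.5, 16, length.out = 100)
  tr <- data.frame(k_local = k, C = 0.61 * k, uturn = FALSE)
  fit <- suppressWarnings(fit_contact_rate(tr))
  expect_equal(fit$slope, 0.61, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # all-zero contacts give a zero slope
  tr0 <- data.frame(k_local = k, C = 0, uturn = FALSE)
  expect_equal(suppressWarnings(fit_contact_rate(tr0))$slope, 0)
  expect_error(fit_contact_rate(data.frame(k_local = rep(0, 50), C = 0)),
               class = "ant_data_error")
  # Poisson-generated records recover the generator slope within 3 SE
  trp <- generate_tracked(8000, config = generator_config(seed = 31))
  fp <- fit_contact_rate(trp)
  expect_lt(abs(fp$slope - 0.61), 3 * fp$se)
})

test_that("travel-time regression recovers intercept and slope", {
  tr <- data.frame(C = rep(0:6, each = 10), uturn = FALSE)
  tr$T <- 0.95 + 0.24 * tr$C
  fit <- suppressWarnings(fit_travel_time(tr))
  expect_equal(coef(fit), c(T0 = 0.95, dT = 0.24), tolerance = 1e-12)
  # constant contact count leaves the slope unidentifiable
  expect_error(fit_travel_time(data.frame(C = rep(2, 50), T = rnorm(50, 1.4))),
               class = "ant_data_error")
  # noisy defaults: both estimates within 3 SE of planted values
  trn <- generate_tracked(8000, config = generator_config(seed = 32),
                          pheromone = FALSE)
  fn <- fit_travel_time(trn)
  expect_lt(abs(fn$T0 - 0.95), 3 * fn$se[["T0"]])
  expect_lt(abs(fn$dT - 0.24), 3 * fn$se[["dT"]])
})

test_that("U-turn records are excluded from the regressions", {
  k <- seq(0.5, 16, length.out = 200)
  tr <- data.frame(k_local = k, C = 0.61 * k, uturn = FALSE)
  tr$T <- 0.95 + 0.24 * tr$C
  spoiled <- tr
  spoiled$uturn[1:50] <- TRUE
  spoiled$C[1:50] <- 40            # would wreck the slope if included
  expect_equal(suppressWarnings(fit_contact_rate(spoiled))$slope,
               suppressWarnings(fit_contact_rate(tr[51:200, ]))$slope)
  expect_equal(suppressWarnings(fit_travel_time(spoiled))$n, 150)
})

test_that("free-flow speed removes contact time and flags invalid records", {
  expect_equal(free_flow_speed(T = 0.95, C = 0), 2 / 0.95,
               ignore_attr = TRUE)
  # contact-corrected crossing equals the free crossing
  expect_equal(free_flow_speed(T = 1.43, C = 2), 2 / 0.95,
               ignore_attr = TRUE, tolerance = 1e-12)
  v <- free_flow_speed(T = c(0.95, 0.4), C = c(0, 2))
  expect_true(is.na(v[2]))
  expect_equal(attr(v, "n_invalid"), 1L)
  expect_error(free_flow_speed(1, 0, dT = -1), class = "ant_config_error")
})

test_that("travel-time curves are flat, ordered, and dip at 1/gamma", {
  p <- micro_params()
  k <- rep(seq(0.2, 16, length.out = 80), times = 3)
  C <- rep(0:2, each = 80)
  # no pheromone effect: each stratum is a constant line
  flat <- data.frame(k_local = k, C = C, T = 0.95 + 0.24 * C, uturn = FALSE)
  cf <- travel_time_curves(flat, contact_levels = 0:2)
  for (lev in 0:2)
    expect_equal(cf$T_fit[cf$C == lev], rep(0.95 + 0.24 * lev, 50),
                 tolerance = 1e-6)
  # pheromone effect on: curves dip at the pheromone optimum 1/gamma
  dip <- data.frame(k_local = k, C = C, uturn = FALSE)
  dip$T <- (p$T0 + p$dT * C) / pheromone_factor(k, p)
  cd <- travel_time_curves(dip, contact_levels = 0:2)
  for (lev in 0:2) {
    cur <- cd[cd$C == lev, ]
    expect_lt(abs(cur$k[which.min(cur$T_fit)] - 1 / p$gamma), 1)
  }
  # more contacts means a longer crossing at every density
  t0 <- cd$T_fit[cd$C == 0]; t1 <- cd$T_fit[cd$C == 1]
  expect_true(all(t1 > t0))
  expect_warning(travel_time_curves(flat, contact_levels = c(0, 9)),
                 "skipped")
})

test_that("speed model and its flow have the published closed forms", {
  p <- micro_params()
  expect_equal(speed_model(0), 2 * 0.812 / 0.95)
  expect_equal(pheromone_factor(0), 0.812)
  # pheromone factor peaks at exactly k = 1/gamma
  opt <- optimize(function(k) pheromone_factor(k, p),
                  c(0, 30), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, 1 / p$gamma, tolerance = 1e-6)
  expect_equal(predict_flow(0), 0)
  # limit flow: closed form, linearity in alpha, and the numeric limit
  expect_equal(limit_flow(), 2 * 0.812 / (0.24 * 0.61))
  p_half <- micro_params(alpha = 0.812 / 2)
  expect_equal(limit_flow(p_half), limit_flow() / 2)
  expect_equal(predict_flow(1e6), limit_flow(), tolerance = 1e-3)
  # gap to the limit shrinks monotonically along a coarse density ladder
  gap <- abs(predict_flow(10^(1:6)) - limit_flow())
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[4], 0.01)
  # flow rises on [0, 8] then varies by < 10% across the plateau
  expect_true(all(diff(predict_flow(seq(0, 8, by = 0.1))) >= 0))
  plateau <- predict_flow(seq(10, 18, by = 0.1))
  expect_lt(diff(range(plateau)) / mean(plateau), 0.10)
  # beta = 0 removes the bump: speed strictly decreasing, same limit
  p0 <- micro_params(beta = 1e-12)
  expect_true(all(diff(speed_model(seq(0, 30, 0.1), p0)) < 0))
  expect_true(all(diff(predict_flow(seq(0, 50, 0.5), p0)) > 0))
  expect_equal(limit_flow(p0), limit_flow(), tolerance = 1e-9)
})

test_that("speed-model fit recovers planted pheromone parameters", {
  planted <- default_planted[c("alpha", "beta", "gamma")]
  # exact mean-model data: recovery to 1e-6
  fit <- fit_speed_model(eq_speed_tracked())
  expect_equal(unname(coef(fit)), unname(planted), tolerance = 1e-6)
  # noisy defaults: within 3 SE
  trn <- generate_tracked(8000, config = generator_config(seed = 33))
  fn <- fit_speed_model(trn)
  expect_true(all(abs(coef(fn) - planted) < 3 * fn$se))
  # records at a single density cannot identify beta and gamma
  tr0 <- data.frame(k_local = rep(0, 100), C = 0, T = rnorm(100, 1.2, 0.05),
                    uturn = FALSE)
  expect_error(fit_speed_model(tr0), class = "ant_data_error")
})

test_that("full microscopic chain recovers all planted constants", {
  tr <- generate_tracked(8000, config = generator_config(seed = 34),
                         pheromone = FALSE)
  trp <- generate_tracked(8000, config = generator_config(seed = 34))
  cr <- fit_contact_rate(trp)
  tt <- fit_travel_time(tr)
  sf <- fit_speed_model(trp)
  est <- c(c = cr$slope, T0 = tt$T0, dT = tt$dT, coef(sf))
  ses <- c(cr$se, tt$se, sf$se)
  expect_true(all(abs(est - default_planted) < 3 * ses))
})
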