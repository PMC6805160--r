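test_that("noiseless two-phase data give back the planted parameters", {
  obs <- two_phase_obs(v = 1.25, k_j = 8)
  fit <- fit_diagram(obs, "two_phase")
  expect_equal(unname(coef(fit)[["v"]]), 1.25, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["k_j"]]), 8, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("noiseless greenshields data give back the planted parameters", {
  k <- seq(0.25, 7.5, by = 0.25)          # below the jam density
  obs <- data.frame(k = k, q = k * greenshields_speed(k, v_f = 1.9, k_j = 8.5))
  fit <- fit_diagram(obs, "greenshields")
  expect_equal(unname(coef(fit)), c(1.9, 8.5), tolerance = 1e-6)
})

test_that("fit_diagram rejects degenerate inputs", {
  expect_error(fit_diagram(two_phase_obs(k = 1:5), "two_phase"),
               class = "ant_data_error")                    # too few points
  obs0 <- data.frame(k = seq(0, 5, by = 0.5), q = 0)
  expect_error(fit_diagram(obs0, "greenshields"), class = "ant_data_error")
  obs_flat <- data.frame(k = rep(2, 20), q = rnorm(20, 2, 0.1))
  expect_error(fit_diagram(obs_flat, "two_phase"), class = "ant_data_error")
  expect_error(fit_diagram(two_phase_obs(), "two_phase", init = c(bogus = 1)),
               class = "ant_config_error")
})

test_that("two-phase fit agrees with a brute-force parameter lattice", {
  k <- seq(0.8, 16, length.out = 20)
  set.seed(11)
  obs <- data.frame(k = k, q = two_phase_flow(k, 1.25, 8) + rnorm(20, 0, 0.2))
  obs$q <- pmax(obs$q, 0)
  lattice <- expand.grid(v = seq(1.0, 1.5, by = 0.005),
                         k_j = seq(6, 10, by = 0.05))
  sse <- mapply(function(v, kj) sum((obs$q - two_phase_flow(k, v, kj))^2),
                lattice$v, lattice$k_j)
  best <- lattice[which.min(sse), ]
  fit <- fit_diagram(obs, "two_phase")
  expect_equal(unname(coef(fit)[["v"]]), best$v, tolerance = 0.005)
  expect_equal(unname(coef(fit)[["k_j"]]), best$k_j, tolerance = 0.05)
  expect_lte(fit$sse, min(sse) + 1e-9)
})

test_that("akaike weights follow the closed-form exp(-delta/2) rule", {
  mk_fit <- function(sse, n, p, model = "two_phase") {
    structure(list(model = fd_model(model), estimates = rep(1, p),
                   se = rep(NA_real_, p), sse = sse, n = n,
                   aic = n * log(sse / n) + 2 * (p + 1),
                   akaike_weight = NA_real_,
                   data = data.frame(k = 1, q = 1)),
              class = "fd_fit")
  }
  # equal SSE and equal parameter count -> equal weights
  w <- akaike_weights(list(mk_fit(50, 100, 2), mk_fit(50, 100, 2)))
  expect_equal(vapply(w, `[[`, numeric(1), "akaike_weight"), c(0.5, 0.5),
               ignore_attr = TRUE)
  # delta AIC of exactly 2 -> weight ratio exp(-1)
  f1 <- mk_fit(50, 100, 2)
  f2 <- mk_fit(50 * exp(2 / 100), 100, 2)   # shifts AIC by exactly +2
  w2 <- vapply(akaike_weights(list(f1, f2)), `[[`, numeric(1),
               "akaike_weight")
  expect_equal(unname(w2[2] / w2[1]), exp(-1), tolerance = 1e-10)
  expect_equal(unname(w2), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  # weights across four real fits sum to one
  obs <- generate_macroscopic(generator_config(seed = 4, duration = 900))
  fits <- lapply(c("two_phase", "greenshields", "pipes_munjal", "underwood"),
                 fit_diagram, obs = obs)
  ws <- vapply(akaike_weights(fits), `[[`, numeric(1), "akaike_weight")
  expect_equal(sum(ws), 1, tolerance = 1e-12)
  expect_true(all(ws >= 0 & ws <= 1))
  expect_error(akaike_weights(list()), class = "ant_config_error")
  expect_error(akaike_weights(list(mk_fit(50, 100, 2), mk_fit(50, 99, 2))),
               class = "ant_data_error")
})

test_that("bin_summary uses half-open bins and flags singleton SDs", {
  obs <- data.frame(k = c(0.1, 0.2, 1.0), q = c(4, 6, 3))
  bs <- bin_summary(obs, bin_width = 0.5)
  expect_equal(nrow(bs), 2)            # empty bin [0.5, 1) omitted
  expect_equal(bs$q_mean[1], 5)
  expect_equal(bs$n, c(2L, 1L))
  expect_true(is.na(bs$q_sd[2]))       # SD undefined for one observation
  expect_equal(bs$k_lo[2], 1.0)        # k = 1.0 falls in [1.0, 1.5)
  expect_error(bin_summary(obs, bin_width = 0), class = "ant_config_error")
})

test_that("bin means of uniform synthetic data track the generating flow", {
  cfg <- generator_config(seed = 8, duration = 5000,
                          density_profile = "uniform", density_max = 16,
                          asym_profile = "constant")
  obs <- generate_macroscopic(cfg)
  bs <- bin_summary(obs, bin_width = 1)
  bs <- bs[bs$n >= 30, ]
  se <- bs$q_sd / sqrt(bs$n)
  expect_true(all(abs(bs$q_mean - predict_flow(bs$k_mid)) < 3 * se))
})
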