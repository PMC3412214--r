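test_that("cut sampling requires data and leaves the population intact", {
  fit <- fx_fit_small()
  expect_error(individual_posterior(fit), "at least one")
  theta_before <- fit$theta + 0 # force a copy
  ind <- individual_posterior(fit, times = 0, values = 50, seed = 31)
  expect_identical(fit$theta, theta_before)
  expect_equal(ind$n_draws, nrow(fit$theta))
})

test_that("noise-free measurements pin the individual's curve", {
  fit <- fx_fit_small()
  # shrink the residual SD to (almost) nothing in the population draws
  fit2 <- fit
  fit2$theta[, "sigma_w"] <- 1e-5
  ind <- individual_posterior(fit2, times = c(0, 2), values = c(40, 46),
                              seed = 32)
  expect_equal(unname(ind$coef[, "A"]), rep(40, ind$n_draws),
               tolerance = 1e-3)
  expect_equal(unname(ind$coef[, "B"]), rep(3, ind$n_draws),
               tolerance = 1e-3)
})

test_that("single large baselines are shrunk toward the population mean", {
  fit <- fx_fit_small()
  ind <- individual_posterior(fit, times = 0, values = 50, seed = 33)
  expect_lt(mean(ind$coef[, "A"]), 50)
  # and its expected growth exceeds the population mean slope (rho > 0)
  expect_gt(mean(ind$coef[, "B"]), median(fit$theta[, "beta1"]))
})

test_that("growth rates follow the curve derivative", {
  ind <- fake_indpost(A = 40, B = 2.19, n_draws = 50)
  g <- growth_rate(ind)
  expect_true(all(g$draws == 2.19))

  indq <- fake_indpost(A = 40, B = 1.5, C = 0.1, n_draws = 50)
  gq <- growth_rate(indq, t = 2)
  expect_true(all(abs(gq$draws - 1.9) < 1e-12))
  expect_error(growth_rate(indq), "t must be given")
})

test_that("threshold times handle the zero, finite and infinite cases", {
  # linear: level 40, slope 3 -> exactly 5 years to 55
  w <- time_to_threshold(fake_indpost(40, 3, n_draws = 3), t = 0,
                         alpha = 55)
  expect_true(all(w$draws == 5))
  # negative growth below the threshold: never crossed
  w <- time_to_threshold(fake_indpost(40, -1, n_draws = 3), alpha = 55)
  expect_true(all(is.infinite(w$draws)))
  expect_equal(w$p_inf, 1)
  # already at or above the threshold at t
  w <- time_to_threshold(fake_indpost(56, 1, n_draws = 3), alpha = 55)
  expect_true(all(w$draws == 0))
  expect_equal(w$p_zero, 1)
  # quadratic: 40 + 2t + 0.1 t^2 = 55 -> positive root of
  # 0.1 W^2 + 2 W - 15 = 0
  wq <- time_to_threshold(fake_indpost(40, 2, 0.1, n_draws = 3),
                          alpha = 55)
  root <- (-2 + sqrt(4 + 4 * 0.1 * 15)) / (2 * 0.1)
  expect_equal(unname(wq$draws), rep(root, 3), tolerance = 1e-12)
  expect_equal(wq$draws[1],
               oracle_time_to_threshold(40, 2, 0.1, 0, 55),
               tolerance = 1e-3)
})

test_that("extended-line summaries order infinity above all reals", {
  draws <- c(1, 2, 3, Inf, Inf)
  ind <- fake_indpost(40, c(15 / 1, 15 / 2, 15 / 3, -1, -2), n_draws = 5)
  w <- time_to_threshold(ind, alpha = 55)
  expect_equal(sort(w$draws), sort(draws))
  expect_equal(w$median, 3) # middle order statistic on the extended line
  expect_equal(w$p_inf, 0.4)
  expect_true(is.infinite(w$upper))
})

test_that("the posterior predictive adds fresh measurement error", {
  ind <- fake_indpost(50, 0, sigma_w = 3.12, n_draws = 4000)
  pm <- predict_measurement(ind, t = 0, s = 1, seed = 34)
  expect_equal(sd(pm$draws), 3.12, tolerance = 0.05)
  expect_equal(mean(pm$draws), 50, tolerance = 0.2)
  # underlying level carries no error and s = 0 returns the current level
  pu <- predict_measurement(ind, t = 0, s = 0, type = "underlying")
  expect_true(all(pu$draws == 50))
})

test_that("exceedance probabilities match the normal tail oracle", {
  ind <- fake_indpost(50, 0, sigma_w = 3.2, n_draws = 10)
  p <- exceedance_prob(ind, t = 0, s = 1, alpha = 55)
  expect_equal(as.vector(p), 1 - pnorm((55 - 50) / 3.2), tolerance = 1e-12)
  expect_equal(as.vector(exceedance_prob(ind, s = 1, alpha = -1e9)), 1)
  # non-decreasing in the horizon for positive-slope draws
  ind2 <- fake_indpost(40, 2, sigma_w = 3, n_draws = 10)
  ps <- exceedance_prob(ind2, s = seq(0, 8, by = 0.5), alpha = 55)
  expect_true(all(diff(ps) >= 0))
})

test_that("longer consistent histories tighten the growth-rate posterior", {
  fit <- fx_fit_small()
  times <- seq(0, 3.5, by = 0.5)
  values <- 42 + 2 * times
  sds <- vapply(c(2, 4, 8), function(k) {
    ind <- individual_posterior(fit, times = times[1:k],
                                values = values[1:k], seed = 35)
    sd(growth_rate(ind)$draws)
  }, 0)
  expect_true(all(diff(sds) <= 0.02))
})

test_that("cut sampling under t errors works through the scale mixture", {
  tp <- truth_params(error_family = "student_t", df = 4)
  sim <- simulate_cohort(generator_config(n_subjects = 60, truth = tp,
                                          entry_filter = "none",
                                          seed = 36))
  fit <- fit_growth(sim$cohort,
                    model_spec("linear", error_family = "student_t"),
                    chains = 1, iter = 400, burnin = 150, seed = 37,
                    keep_b = FALSE)
  ind <- individual_posterior(fit, times = c(0, 1), values = c(45, 48),
                              seed = 38)
  expect_true(all(is.finite(ind$coef[, c("A", "B")])))
  # an extreme single measurement is discounted more than under gauss:
  # just check the machinery returns sane levels near the data
  expect_gt(mean(ind$coef[, "A"]), 35)
  expect_lt(mean(ind$coef[, "A"]), 50)
})

test_that("in-sample prediction reuses the stored random effects", {
  fit <- fx_fit_small()
  sim <- fx_sim_small()
  id <- fit$subject_ids[1]
  ind <- individual_posterior(fit, subject_id = id)
  b0 <- fit$b[, 1, 1]
  expect_equal(unname(ind$coef[, "A"]),
               unname(fit$theta[, "beta0"] + b0))
})
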