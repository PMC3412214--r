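test_that("random effects reproduce the generating covariance", {
  set.seed(99)
  b <- draw_subject_effects(truth_params(), 1e5)
  expect_equal(cor(b[, 1], b[, 2]), 0.51, tolerance = 0.01 / 0.51)
  expect_equal(sd(b[, 1]), 7.12, tolerance = 0.01)
  expect_equal(sd(b[, 2]), 1.74, tolerance = 0.01)

  # degenerate covariance gives exactly zero effects
  b0 <- draw_subject_effects(truth_params(sds = c(0, 0), rhos = 0), 10)
  expect_true(all(b0 == 0))
})

test_that("the skewed baseline law is right-skewed on [30, 55)", {
  set.seed(98)
  tp <- truth_params(baseline_law = "skewed")
  b <- draw_subject_effects(tp, 2e4)
  lvl <- tp$beta[1] + b[, 1]
  expect_true(all(lvl >= 30 & lvl < 55))
  skew <- mean(((lvl - mean(lvl)) / sd(lvl))^3)
  expect_gt(skew, 0.3)
  expect_equal(mean(lvl), 37.5, tolerance = 0.01)
  # slope effects keep their conditional-normal relation to the intercept
  expect_gt(cor(b[, 1], b[, 2]), 0.3)
})

test_that("a noiseless subject lies exactly on the population line", {
  set.seed(1)
  tp <- truth_params(beta = c(40, 2), sds = c(0, 0), rhos = 0, sigma_w = 0)
  sub <- simulate_subject(tp, schedule_rule(jitter_sd = 0,
                                            attendance_prob = 1),
                          dropout_rule(death_rate = 0, loss_rate = 0,
                                       admin_horizon = 6))
  expect_equal(sub$measurements$value, 40 + 2 * sub$measurements$time)
})

test_that("scan intervals follow the diameter bands", {
  set.seed(2)
  # flat, noise-free trajectories pin the observed value
  mk <- function(level) {
    tp <- truth_params(beta = c(level, 0), sds = c(0, 0), rhos = 0,
                       sigma_w = 0)
    sub <- simulate_subject(tp, schedule_rule(jitter_sd = 0,
                                              attendance_prob = 1),
                            dropout_rule(death_rate = 0, loss_rate = 0,
                                         admin_horizon = 3))
    diff(sub$measurements$time)
  }
  expect_equal(unique(mk(40)), 1)     # 30-44 mm: annual
  expect_equal(unique(mk(47)), 0.25)  # 45-54 mm: 3-monthly
})

test_that("observed diameters at or over 55 mm trigger surgery", {
  set.seed(3)
  tp <- truth_params(beta = c(50, 6), sds = c(0, 0), rhos = 0,
                     sigma_w = 0.1)
  sub <- simulate_subject(tp, schedule_rule(),
                          dropout_rule(referral_prob = 1,
                                       death_rate = 0, loss_rate = 0,
                                       admin_horizon = 30))
  expect_identical(sub$termination, "surgery")
  last <- nrow(sub$measurements)
  dy <- diff(sub$measurements$value)
  expect_true(sub$measurements$value[last] >= 55 ||
                any(dy >= 10))
})

test_that("cohorts are reproducible and prefix-stable in the seed", {
  cfg <- generator_config(n_subjects = 30, seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$measurements, s2$cohort$measurements)
  expect_identical(s1$b, s2$b)

  big <- simulate_cohort(generator_config(n_subjects = 60, seed = 11))
  keep <- big$cohort$measurements$subject_id %in%
    unique(s1$cohort$measurements$subject_id)
  bigm <- big$cohort$measurements[keep, ]
  rownames(bigm) <- NULL
  expect_identical(s1$cohort$measurements, bigm)
})

test_that("no two scans of a subject are closer than the minimum gap", {
  sim <- fx_sim_default()
  gaps <- tapply(sim$cohort$measurements$time,
                 sim$cohort$measurements$subject_id, function(t) {
                   if (length(t) > 1) min(diff(sort(t))) else Inf
                 })
  expect_gte(min(gaps), 0.05 - 1e-12)
})

test_that("an infeasible entry filter reports rejection counts", {
  cfg <- generator_config(n_subjects = 2,
                          truth = truth_params(beta = c(150, 0),
                                               sds = c(0, 0), rhos = 0,
                                               sigma_w = 0.1),
                          seed = 5)
  expect_error(simulate_cohort(cfg), "rejected 1000")
})

test_that("the censoring entry filter emits sub-30 mm screens as bounds", {
  tc <- truth_params(beta = c(28, 2.19), sds = c(6, 1.74), rhos = 0.51)
  sim <- simulate_cohort(generator_config(n_subjects = 50, truth = tc,
                                          entry_filter = "censor",
                                          seed = 6))
  m <- sim$cohort$measurements
  expect_gt(sum(!is.na(m$censor_bound)), 0)
  expect_true(all(m$censor_bound[!is.na(m$censor_bound)] == 30))
  expect_true(all(is.na(m$value[!is.na(m$censor_bound)])))
  # followed subjects entered at 30-54 mm observed
  first <- m[!is.na(m$value), ]
  first <- first[!duplicated(first$subject_id), ]
  expect_true(all(first$value >= 30 & first$value < 55))
})
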