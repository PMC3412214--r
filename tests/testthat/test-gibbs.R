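test_that("the fixed-effect block matches the closed-form posterior", {
  # with random effects pinned at zero and a known residual SD, the
  # sampled beta posterior must equal the conjugate normal-regression
  # posterior
  set.seed(10)
  n <- 40
  t <- rep(c(0, 1, 2), n)
  id <- rep(seq_len(n), each = 3)
  y <- 37 + 2 * t + rnorm(3 * n)
  d <- aaa_cohort(data.frame(subject_id = paste0("s", id),
                             time = t + rep(seq_len(n) * 1e-6, each = 3),
                             value = y))
  fit <- fit_growth(d, model_spec("linear"), chains = 1, iter = 5000,
                    burnin = 500, seed = 11, keep_b = FALSE,
                    fix_b = TRUE, fix_sigma_w = 1)
  dat <- aaamonitor:::.fit_data(d, model_spec("linear"))
  X <- dat$X
  V <- solve(crossprod(X) + diag(1e-6, 2))
  m <- V %*% crossprod(X, dat$y)
  draws <- fit$theta[, c("beta0", "beta1")]
  mcse <- apply(draws, 2, sd) / sqrt(nrow(draws) / 10) # conservative ESS
  expect_lt(abs(mean(draws[, 1]) - m[1]), 5 * mcse[1])
  expect_lt(abs(mean(draws[, 2]) - m[2]), 5 * mcse[2])
  expect_equal(sd(draws[, 1]), sqrt(V[1, 1]), tolerance = 0.1)
  expect_equal(sd(draws[, 2]), sqrt(V[2, 2]), tolerance = 0.1)
})

test_that("with negligible noise the posterior pins the generating line", {
  tp <- truth_params(beta = c(40, 2), sds = c(0, 0), rhos = 0,
                     sigma_w = 0.01)
  sim <- simulate_cohort(generator_config(n_subjects = 50, truth = tp,
                                          entry_filter = "none",
                                          seed = 12))
  fit <- fit_growth(sim$cohort, model_spec("linear"), chains = 2,
                    iter = 600, burnin = 200, seed = 13, keep_b = FALSE)
  s <- summary(fit)
  expect_lt(abs(s["beta0", "median"] - 40), 2 * s["beta0", "sd"] + 0.01)
  expect_lt(abs(s["beta1", "median"] - 2), 2 * s["beta1", "sd"] + 0.01)
})

test_that("a single-subject dataset runs and shrinks its effects", {
  d <- tiny_cohort(c(0, 1), c(48, 50))
  fit <- fit_growth(d, model_spec("linear"), chains = 2, iter = 400,
                    burnin = 100, seed = 14)
  # with one subject the random effect is identified mostly by the prior:
  # the fitted intercept deviation stays modest
  expect_true(all(is.finite(fit$theta)))
  expect_true(all(fit$theta[, "sigma_w"] > 0))
})

test_that("posterior draws respect their parameter constraints", {
  fit <- fx_fit_small()
  expect_true(all(fit$theta[, "sigma_w"] > 0))
  expect_true(all(fit$theta[, c("sigma0", "sigma1")] > 0))
  expect_true(all(abs(fit$theta[, "rho01"]) < 1))
  # implied 2x2 covariance draws are positive definite
  det2 <- fit$theta[, "sigma0"]^2 * fit$theta[, "sigma1"]^2 *
    (1 - fit$theta[, "rho01"]^2)
  expect_true(all(det2 > 0))
})

test_that("fits are bit-reproducible under a fixed seed", {
  d <- fx_sim_small()$cohort
  f1 <- fit_growth(d, model_spec("linear"), chains = 1, iter = 200,
                   burnin = 50, seed = 21, keep_b = FALSE)
  f2 <- fit_growth(d, model_spec("linear"), chains = 1, iter = 200,
                   burnin = 50, seed = 21, keep_b = FALSE)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ll, f2$ll)
})

test_that("the t-error sampler keeps nu inside its prior support", {
  tp <- truth_params(error_family = "student_t", df = 4)
  sim <- simulate_cohort(generator_config(n_subjects = 80, truth = tp,
                                          entry_filter = "none",
                                          seed = 15))
  fit <- fit_growth(sim$cohort,
                    model_spec("linear", error_family = "student_t"),
                    chains = 1, iter = 400, burnin = 150, seed = 16,
                    keep_b = FALSE)
  expect_true(all(fit$theta[, "nu"] >= 2))
  expect_true(all(fit$theta[, "nu"] <= 1000))
  # heavy-tailed truth: most nu mass should sit far below the upper bound
  expect_lt(median(fit$theta[, "nu"]), 50)
})

test_that("covariate effects on intercept and slope are recovered", {
  tp <- truth_params(gamma = list(smoke = c(2.5, 0.8)))
  covgen <- function(n) data.frame(smoke = rbinom(n, 1, 0.5))
  sim <- simulate_cohort(generator_config(n_subjects = 400, truth = tp,
                                          entry_filter = "none",
                                          covariate_gen = covgen,
                                          seed = 17))
  fit <- fit_growth(sim$cohort, model_spec("linear", covariates = "smoke"),
                    chains = 2, iter = 1200, burnin = 400, seed = 18,
                    keep_b = FALSE)
  s <- summary(fit)
  expect_lt(abs(s["smoke_int", "median"] - 2.5), 3 * s["smoke_int", "sd"])
  expect_lt(abs(s["smoke_slope", "median"] - 0.8),
            3 * s["smoke_slope", "sd"])
})

test_that("REML point estimates agree with the posterior (external check)", {
  skip_if_not_installed("lme4")
  sim <- fx_sim_small()
  fit <- fx_fit_small()
  m <- sim$cohort$measurements
  re <- lme4::lmer(value ~ time + (time | subject_id), data = m,
                   REML = TRUE)
  fe <- lme4::fixef(re)
  s <- summary(fit)
  expect_lt(abs(s["beta0", "median"] - fe[["(Intercept)"]]),
            3 * s["beta0", "sd"])
  expect_lt(abs(s["beta1", "median"] - fe[["time"]]),
            3 * s["beta1", "sd"])
  expect_equal(s["sigma_w", "median"], sigma(re), tolerance = 0.05)
})

test_that("nominal 90% intervals for the mean slope calibrate correctly", {
  # reduced simulation-based calibration: 100 small replicates
  covered <- logical(100)
  for (r in seq_len(100)) {
    sim <- simulate_cohort(generator_config(n_subjects = 30,
                                            entry_filter = "none",
                                            seed = 3000 + r))
    fit <- fit_growth(sim$cohort, model_spec("linear"), chains = 1,
                      iter = 500, burnin = 200, seed = 4000 + r,
                      keep_b = FALSE)
    ci <- quantile(fit$theta[, "beta1"], c(0.05, 0.95))
    covered[r] <- ci[1] <= 2.19 && 2.19 <= ci[2]
  }
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.95)
})

test_that("independent intercepts show no shrinkage relative to L1", {
  sim <- fx_sim_small()
  f2 <- fit_growth(sim$cohort,
                   model_spec("linear", intercept_model = "independent"),
                   chains = 1, iter = 800, burnin = 300, seed = 19,
                   keep_b = FALSE)
  f1 <- fx_fit_small()
  expect_gte(median(f2$theta[, "sigma0"]),
             median(f1$theta[, "sigma0"]))
  expect_true(all(f2$theta[, "lambda"] > -5 & f2$theta[, "lambda"] < 5))
})
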