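test_that("a simple delimited file parses into subjects and measurements", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,value",
               "a,0,35.2", "a,1,37.1", "a,2,39.0"), path)
  d <- read_cohort(path)
  expect_s3_class(d, "aaa_cohort")
  expect_equal(nrow(d$subjects), 1L)
  expect_equal(d$measurements$time, c(0, 1, 2))
  expect_equal(d$measurements$value, c(35.2, 37.1, 39.0))
})

test_that("invalid rows are rejected with informative errors", {
  base <- data.frame(subject_id = "a", time = 0, value = 35)
  expect_error(aaa_cohort(rbind(base, base)), "duplicate")
  expect_error(aaa_cohort(transform(base, time = -1)), "non-negative")
  expect_error(
    aaa_cohort(data.frame(subject_id = "a", time = 0, value = 35,
                          censor_bound = 30)),
    "exactly one")
  expect_error(
    aaa_cohort(data.frame(subject_id = "a", time = 0, value = NA_real_)),
    "exactly one|non-censored")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,value", "a,0,abc"), path)
  expect_error(read_cohort(path), "non-numeric")
})

test_that("write/read round-trips a synthetic cohort exactly", {
  sim <- simulate_cohort(generator_config(n_subjects = 100, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_identical(back$measurements, sim$cohort$measurements)
  expect_identical(back$subjects, sim$cohort$subjects)
})

test_that("covariates and censored records survive the round trip", {
  m <- data.frame(subject_id = c("a", "a", "b", "c"),
                  time = c(0, 1.25, 0, 0),
                  value = c(31.5, 33.25, 40, NA),
                  censor_bound = c(NA, NA, NA, 30))
  s <- data.frame(subject_id = c("a", "b", "c"),
                  termination = c("surgery", NA, NA),
                  smoke = c(1, 0, 0.5), age65 = c(2.5, -1, 0))
  d <- aaa_cohort(m, s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_true(all(c("censor_bound", "smoke", "age65") %in% hdr))
  back <- read_cohort(path)
  expect_identical(back$measurements, d$measurements)
  expect_identical(back$subjects, d$subjects)

  # no covariates, no censoring: the extra columns are not emitted
  d2 <- tiny_cohort(c(0, 1), c(35, 37))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d2, path2)
  expect_identical(strsplit(readLines(path2, n = 1L), ",")[[1]],
                   c("subject_id", "time", "value"))
})

test_that("cohort summaries compute scans, follow-up and histograms", {
  m <- expand.grid(subject_id = paste0("s", 1:5), j = 1:8)
  m$time <- (m$j - 1) * 0.7
  m$value <- 35 + m$time
  d <- aaa_cohort(m[c("subject_id", "time", "value")])
  s <- summarize_cohort(d)
  expect_equal(s$mean_scans, 8)
  expect_equal(s$n_subjects, 5L)
  expect_equal(s$mean_followup, 7 * 0.7)

  d1 <- tiny_cohort(c(0, 4.9), c(35, 45))
  expect_equal(summarize_cohort(d1)$mean_followup, 4.9)
})

test_that("summaries are invariant to subject ordering", {
  sim <- simulate_cohort(generator_config(n_subjects = 50, seed = 3))
  m <- sim$cohort$measurements
  perm <- m[rev(seq_len(nrow(m))), ]
  d2 <- aaa_cohort(perm, sim$cohort$subjects)
  s1 <- summarize_cohort(sim$cohort)
  s2 <- summarize_cohort(d2)
  expect_equal(s1$mean_scans, s2$mean_scans)
  expect_equal(s1$mean_followup, s2$mean_followup)
  expect_equal(s1$baseline_hist, s2$baseline_hist)
})

test_that("the default generator reproduces screening-study descriptives", {
  s <- summarize_cohort(fx_sim_default()$cohort)
  expect_gte(s$mean_scans, 7)
  expect_lte(s$mean_scans, 10)
  expect_gt(s$mean_followup, 3.5)
  surg <- as.numeric(s$termination[["surgery"]])
  expect_gte(surg, 0.2)
  expect_lte(surg, 0.5)
})
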