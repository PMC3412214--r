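# Shared fixtures, built once per test run and memoised.  Small cohorts and
# fits used across unit tests; the heavyweight acceptance fits live in
# helper-acceptance.R.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, expr, envir = .fx)
  get(name, envir = .fx)
}

# MASS-like cohort simulated exactly from the default linear truth
fx_sim_small <- function() {
  memo("sim_small", simulate_cohort(
    generator_config(n_subjects = 200, entry_filter = "none", seed = 42)))
}

# linear fit of the small cohort
fx_fit_small <- function() {
  memo("fit_small", fit_growth(fx_sim_small()$cohort, model_spec("linear"),
                               chains = 2, iter = 1000, burnin = 300,
                               seed = 43))
}

# default-config cohort (entry-filtered) for generator calibration checks
fx_sim_default <- function() {
  memo("sim_default",
       simulate_cohort(generator_config(n_subjects = 300, seed = 44)))
}

# Hand-built individual posterior with draws fixed at given coefficients;
# used to unit-test prediction arithmetic against closed forms.
fake_indpost <- function(A, B, C = 0, sigma_w = 3.12, n_draws = NULL,
                         trend = if (all(C == 0)) "linear" else "quadratic",
                         error_family = "gaussian", nu = NULL) {
  K <- n_draws %||% max(length(A), length(B), length(C), length(sigma_w))
  structure(
    list(coef = cbind(A = rep_len(A, K), B = rep_len(B, K),
                      C = rep_len(C, K)),
         sigma_w = rep_len(sigma_w, K),
         nu = if (!is.null(nu)) rep_len(nu, K) else NULL,
         trend = trend, error_family = error_family, n_draws = K,
         data = list()),
    class = "aaa_indpost")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small cohort built by hand from explicit measurement rows
tiny_cohort <- function(times, values, ids = "s1") {
  aaa_cohort(data.frame(subject_id = rep_len(ids, length(times)),
                        time = times, value = values))
}
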