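#' Specify a hierarchical growth model
#'
#' The model family follows the Bayesian growth-curve analyses used for
#' screened AAA cohorts:
#'
#' * `L1` — linear trend, bivariate-normal random intercept and slope
#'   (`trend = "linear"`);
#' * `Q1` — quadratic trend, trivariate-normal random effects
#'   (`trend = "quadratic"`);
#' * covariate variants — baseline covariates entering the intercept and
#'   slope (and curvature, if quadratic);
#' * `L2` — independent, unmodelled intercepts (uniform priors, no
#'   shrinkage), slopes Gaussian conditional on the intercepts
#'   (`intercept_model = "independent"`, linear trend only);
#' * `L1-T` — Student-t measurement errors with the degrees of freedom
#'   estimated (`error_family = "student_t"`);
#' * left-censored variant — records known only to lie below a bound
#'   contribute a normal-CDF likelihood term, handled in the sampler by
#'   data augmentation (`censoring = "below_bound"`).
#'
#' @param trend `"linear"` or `"quadratic"`.
#' @param covariates character vector of subject-level covariate names;
#'   each enters the intercept and slope (and curvature) with its own
#'   coefficient.
#' @param intercept_model `"shared_normal"` (default) or `"independent"`.
#' @param error_family `"gaussian"` or `"student_t"` (degrees of freedom
#'   estimated under a uniform prior).
#' @param censoring `"off"` or `"below_bound"`.
#' @param censor_bound the left-censoring bound in mm (default 30, the
#'   diameter defining an aneurysm).
#' @return an object of class `aaa_model`.
#' @export
model_spec <- function(trend = c("linear", "quadratic"),
                       covariates = character(0),
                       intercept_model = c("shared_normal", "independent"),
                       error_family = c("gaussian", "student_t"),
                       censoring = c("off", "below_bound"),
                       censor_bound = 30) {
  trend <- match.arg(trend)
  intercept_model <- match.arg(intercept_model)
  error_family <- match.arg(error_family)
  censoring <- match.arg(censoring)
  if (intercept_model == "independent") {
    if (trend != "linear") {
      stop("independent intercepts are defined for the linear model only",
           call. = FALSE)
    }
    if (error_family != "gaussian" || censoring != "off" ||
        length(covariates)) {
      stop("the independent-intercept model supports gaussian errors, no ",
           "censoring and no covariates", call. = FALSE)
    }
  }
  if (censoring == "below_bound" && error_family != "gaussian") {
    stop("left censoring is implemented for gaussian errors", call. = FALSE)
  }
  structure(list(trend = trend, covariates = as.character(covariates),
                 intercept_model = intercept_model,
                 error_family = error_family, censoring = censoring,
                 censor_bound = censor_bound,
                 d = if (trend == "linear") 2L else 3L),
            class = "aaa_model")
}

#' Prior specification for the hierarchical growth models
#'
#' Defaults are the vague priors used in the AAA analyses: independent
#' `N(0, tau^2)` with `tau = 1000` on all fixed effects, `IG(0.001, 0.001)`
#' on the residual variance, an inverse-Wishart on the random-effect
#' covariance with degrees of freedom `1 + dim(Sigma)` (which induces
#' marginal uniform correlations) and identity scale, `U(-5, 5)` on the
#' slope-on-intercept regression coefficient of the independent-intercept
#' model, `U(0, 1000)` on its intercepts, and `U(2, 1000)` on the Student-t
#' degrees of freedom.
#'
#' @param tau_fixed prior SD of the fixed effects.
#' @param sigma_w_shape,sigma_w_rate inverse-gamma shape/rate on the
#'   residual variance.
#' @param wishart_df_offset inverse-Wishart degrees of freedom are
#'   `wishart_df_offset + dim(Sigma)`.
#' @param wishart_scale inverse-Wishart scale matrix; `NULL` for identity.
#' @param lambda_bounds support of the uniform prior on lambda
#'   (independent-intercept model).
#' @param intercept_bounds support of the uniform prior on each independent
#'   intercept.
#' @param df_bounds support of the uniform prior on the t degrees of
#'   freedom.
#' @return an object of class `aaa_prior`.
#' @export
prior_spec <- function(tau_fixed = 1000,
                       sigma_w_shape = 0.001, sigma_w_rate = 0.001,
                       wishart_df_offset = 1, wishart_scale = NULL,
                       lambda_bounds = c(-5, 5),
                       intercept_bounds = c(0, 1000),
                       df_bounds = c(2, 1000)) {
  stopifnot(tau_fixed > 0, sigma_w_shape > 0, sigma_w_rate > 0,
            wishart_df_offset >= 1,
            lambda_bounds[1] < lambda_bounds[2],
            intercept_bounds[1] < intercept_bounds[2],
            df_bounds[1] >= 2, df_bounds[1] < df_bounds[2])
  structure(list(tau_fixed = tau_fixed, sigma_w_shape = sigma_w_shape,
                 sigma_w_rate = sigma_w_rate,
                 wishart_df_offset = wishart_df_offset,
                 wishart_scale = wishart_scale,
                 lambda_bounds = lambda_bounds,
                 intercept_bounds = intercept_bounds,
                 df_bounds = df_bounds),
            class = "aaa_prior")
}

# Assemble the arrays the samplers work on.  Rows are all measurement rows
# (observed first classified by is_cens); censored rows are dropped with a
# warning when the model ignores censoring.
.fit_data <- function(cohort, model) {
  m <- cohort$measurements
  if (model$censoring == "off" && any(!is.na(m$censor_bound))) {
    warning("cohort contains censored records; ignored because the model ",
            "has censoring = \"off\"", call. = FALSE)
    m <- m[is.na(m$censor_bound), , drop = FALSE]
  }
  if (model$censoring == "below_bound" && all(is.na(m$censor_bound))) {
    warning("censoring = \"below_bound\" but the cohort has no censored ",
            "records", call. = FALSE)
  }
  ids <- unique(m$subject_id)
  id <- match(m$subject_id, ids)
  is_cens <- !is.na(m$censor_bound)
  t <- m$time
  d <- model$d
  X <- if (d == 2L) cbind(1, t) else cbind(1, t, t * t)
  Z <- .cohort_covariates(cohort, ids, model$covariates)
  W <- NULL
  if (!is.null(Z)) {
    Zrow <- Z[id, , drop = FALSE]
    W <- do.call(cbind, lapply(seq_len(ncol(Z)), function(k) {
      if (d == 2L) cbind(Zrow[, k], t * Zrow[, k])
      else cbind(Zrow[, k], t * Zrow[, k], t * t * Zrow[, k])
    }))
    comp <- if (d == 2L) c("int", "slope") else c("int", "slope", "curv")
    colnames(W) <- as.vector(t(outer(model$covariates, comp, paste,
                                     sep = "_")))
  }
  list(y = m$value, t = t, id = id, ids = ids, n = length(ids),
       N = nrow(m), is_cens = is_cens, bound = m$censor_bound,
       X = X, W = W, Z = Z, d = d, q = if (is.null(W)) 0L else ncol(W))
}
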