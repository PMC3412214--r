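#' Gelman–Rubin convergence diagnostic
#'
#' Computes the split-chain potential scale reduction factor for every
#' population parameter: each chain is halved, and the classic
#' between/within variance ratio \eqn{\sqrt{((N-1)/N \, W + B/N) / W}} is
#' formed over the resulting half-chains.  Values close to 1 indicate that
#' the chains have mixed; the conventional working threshold used in this
#' package is 1.05.
#'
#' @param fit an `aaa_fit` with at least two chains, or a numeric matrix of
#'   draws (iterations x parameters) together with `chain`.
#' @param chain integer chain index per row when `fit` is a matrix.
#' @return named vector of R-hat values.
#' @export
rhat <- function(fit, chain = NULL) {
  if (inherits(fit, "aaa_fit")) {
    theta <- fit$theta
    chain <- fit$chain
  } else {
    theta <- as.matrix(fit)
  }
  if (is.null(chain) || length(unique(chain)) < 2L) {
    stop("R-hat requires at least two chains", call. = FALSE)
  }
  # split each chain in half
  split_id <- unlist(lapply(split(seq_along(chain), chain), function(idx) {
    half <- rep(1:2, each = ceiling(length(idx) / 2))[seq_along(idx)]
    paste0(chain[idx], ".", half)
  }))
  split_id <- split_id[order(unlist(split(seq_along(chain), chain)))]
  groups <- split(seq_along(split_id), split_id)
  if (min(lengths(groups)) < 5L) {
    stop("too few retained draws per half-chain", call. = FALSE)
  }
  apply(theta, 2, function(x) {
    if (sd(x) == 0) return(1)
    means <- vapply(groups, function(g) mean(x[g]), 0)
    vars <- vapply(groups, function(g) var(x[g]), 0)
    m <- length(groups)
    nn <- mean(lengths(groups))
    B <- nn * var(means)
    W <- mean(vars)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  })
}

#' Conditional log-likelihood of a parameter draw
#'
#' Evaluates the log-likelihood of the data conditional on a full parameter
#' state (fixed effects, covariate effects, subject random effects and the
#' residual scale) — the deviance scale used for DIC.  Observed rows
#' contribute the error density (normal or scaled t); left-censored rows
#' contribute the log CDF at their bound, \eqn{\log \Phi((c - \mu)/\sigma_w)}.
#'
#' @param cohort an [aaa_cohort].
#' @param model an [model_spec()] (`intercept_model = "shared_normal"`).
#' @param beta fixed-effect vector (length 2 or 3 to match the trend).
#' @param b matrix of random effects, one row per subject in the order of
#'   the cohort's unique subject ids (see `fit$subject_ids`).
#' @param sigma_w residual SD.
#' @param gamma named vector of covariate effects, names matching the
#'   columns built from `model$covariates` (e.g. `smoke_int`,
#'   `smoke_slope`); `NULL` when the model has none.
#' @param nu degrees of freedom for Student-t errors.
#' @return scalar log-likelihood.
#' @export
loglik_point <- function(cohort, model, beta, b, sigma_w, gamma = NULL,
                         nu = NULL) {
  dat <- .fit_data(cohort, model)
  stopifnot(length(beta) == dat$d, nrow(b) == dat$n, ncol(b) == dat$d)
  mu <- drop(dat$X %*% beta) +
    rowSums(dat$X * b[dat$id, , drop = FALSE])
  if (dat$q > 0L) {
    if (is.null(gamma) || !all(colnames(dat$W) %in% names(gamma))) {
      stop("gamma must name every covariate effect: ",
           paste(colnames(dat$W), collapse = ", "), call. = FALSE)
    }
    mu <- mu + drop(dat$W %*% gamma[colnames(dat$W)])
  }
  .loglik_state(dat, model, mu, sigma_w^2, nu)
}

#' Deviance information criterion
#'
#' Computes the conditional-focus DIC of a fitted model:
#' \eqn{\bar D} is the posterior mean of \eqn{-2 \log L(\theta, b)} over the
#' stored draws, the effective number of parameters is
#' \eqn{p_D = \bar D - D(\bar\theta, \bar b)} (deviance at the posterior
#' means of the fixed effects, random effects, residual scale and, for t
#' errors, degrees of freedom), and \eqn{DIC = \bar D + p_D}.  Conditioning
#' the deviance on the random effects makes \eqn{p_D} of the order of the
#' number of subjects, which is the focus appropriate for subject-level
#' prediction.
#'
#' @param fit an `aaa_fit`.
#' @param cohort the cohort it was fitted to.
#' @return a list of class `aaa_dic` with `Dbar`, `pD` and `DIC`.
#' @export
dic <- function(fit, cohort) {
  stopifnot(inherits(fit, "aaa_fit"))
  Dbar <- mean(-2 * fit$ll)
  th <- colMeans(fit$theta)
  model <- fit$model
  if (model$intercept_model == "independent") {
    dat <- .fit_data(cohort, model_spec("linear"))
    mu <- fit$b_mean[dat$id, 1L] +
      (th[["beta1"]] + fit$b_mean[dat$id, 2L]) * dat$t
    Dhat <- -2 * .loglik_state(dat, list(error_family = "gaussian"),
                               mu, th[["sigma_w"]]^2)
  } else {
    d <- model$d
    beta <- th[paste0("beta", seq_len(d) - 1L)]
    gamma <- NULL
    if (length(model$covariates)) {
      comp <- if (d == 2L) c("int", "slope") else c("int", "slope", "curv")
      gn <- as.vector(t(outer(model$covariates, comp, paste, sep = "_")))
      gamma <- th[gn]
    }
    Dhat <- -2 * loglik_point(cohort, model, beta, fit$b_mean,
                              th[["sigma_w"]], gamma = gamma,
                              nu = if (model$error_family == "student_t") {
                                th[["nu"]]
                              } else NULL)
  }
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, pD = pD, DIC = Dbar + pD),
            class = "aaa_dic")
}

#' @export
print.aaa_dic <- function(x, ...) {
  cat(sprintf("Dbar = %.1f   pD = %.1f   DIC = %.1f\n",
              x$Dbar, x$pD, x$DIC))
  invisible(x)
}
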