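#' Individual-level posterior under cut semantics
#'
#' Estimates the random effects of one individual conditional on that
#' individual's measurements and on each stored population draw, without
#' feeding the individual's data back into the population posterior (the
#' "cut"): for every retained draw of \eqn{\theta} one draw of \eqn{b_i}
#' is sampled from \eqn{p(b_i \mid y_i, t_i, \theta)}.  Under gaussian
#' errors this conditional is multivariate normal and is sampled exactly;
#' under Student-t errors it is sampled by a short inner Gibbs run on the
#' scale-mixture representation, keeping the final state.  For the
#' independent-intercept model the individual's intercept has a flat prior
#' and the slope its conditional-gaussian model, giving again an exact
#' normal conditional.  The population draws are returned untouched by
#' construction.
#'
#' For an individual already in the fitted cohort, pass `subject_id` to
#' reuse the stored in-sample random-effect draws instead (requires
#' `keep_b = TRUE` at fitting time).
#'
#' @param fit an `aaa_fit`.
#' @param times,values the individual's measurement times (years) and
#'   diameters (mm); at least one measurement.
#' @param covariates named numeric vector of the individual's baseline
#'   covariates; required when the model has covariates.
#' @param subject_id reuse the stored draws of this in-sample subject
#'   (`times`/`values` are then ignored).
#' @param inner_iter inner Gibbs steps per draw for Student-t errors.
#' @param seed optional seed for the sampling.
#' @return an object of class `aaa_indpost`: per-draw growth-curve
#'   coefficients (`coef` columns `A`, `B`, `C`, the level being
#'   `A + B u + C u^2` at time `u`), per-draw residual scale `sigma_w` and,
#'   for t errors, `nu`.
#' @export
individual_posterior <- function(fit, times = NULL, values = NULL,
                                 covariates = NULL, subject_id = NULL,
                                 inner_iter = 5L, seed = NULL) {
  stopifnot(inherits(fit, "aaa_fit"))
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  th <- fit$theta
  K <- nrow(th)
  d <- if (model$intercept_model == "independent") 2L else model$d

  # covariate contributions to each curve component, per draw
  zoff <- matrix(0, K, 3L)
  if (length(model$covariates)) {
    z <- covariates[model$covariates]
    if (anyNA(z)) {
      stop("individual lacks covariates required by the model: ",
           paste(model$covariates, collapse = ", "), call. = FALSE)
    }
    comp <- if (model$d == 2L) c("int", "slope") else
      c("int", "slope", "curv")
    for (k in seq_along(model$covariates)) {
      for (j in seq_along(comp)) {
        zoff[, j] <- zoff[, j] +
          th[, paste(model$covariates[k], comp[j], sep = "_")] * z[[k]]
      }
    }
  }

  if (!is.null(subject_id)) {
    if (is.null(fit$b)) {
      stop("fit was run with keep_b = FALSE; in-sample draws unavailable",
           call. = FALSE)
    }
    i <- match(subject_id, fit$subject_ids)
    if (is.na(i)) stop("unknown subject_id", call. = FALSE)
    b <- fit$b[, i, ]
  } else {
    if (is.null(times) || length(times) < 1L ||
        length(times) != length(values)) {
      stop("at least one (time, value) measurement is required",
           call. = FALSE)
    }
    b <- .cut_sample(fit, times, values, zoff, inner_iter)
  }

  if (model$intercept_model == "independent") {
    A <- b[, 1L]
    B <- th[, "beta1"] + b[, 2L]
    C <- rep(0, K)
  } else {
    A <- th[, "beta0"] + b[, 1L] + zoff[, 1L]
    B <- th[, "beta1"] + b[, 2L] + zoff[, 2L]
    C <- if (model$d == 3L) th[, "beta2"] + b[, 3L] + zoff[, 3L] else
      rep(0, K)
  }
  structure(
    list(coef = cbind(A = A, B = B, C = C),
         sigma_w = th[, "sigma_w"],
         nu = if (model$error_family == "student_t") th[, "nu"] else NULL,
         trend = model$trend, error_family = model$error_family,
         n_draws = K,
         data = if (is.null(subject_id)) {
           list(times = times, values = values)
         } else list(subject_id = subject_id)),
    class = "aaa_indpost"
  )
}

# One b_i draw per population draw, conditional on the individual's data.
.cut_sample <- function(fit, times, values, zoff, inner_iter) {
  model <- fit$model
  th <- fit$theta
  K <- nrow(th)
  t <- as.numeric(times)
  y <- as.numeric(values)
  m <- length(y)
  sw2 <- th[, "sigma_w"]^2

  if (model$intercept_model == "independent") {
    # flat-prior intercept + conditional-gaussian slope effect
    abar <- th[, "beta0"]
    lam <- th[, "lambda"]
    sc2 <- th[, "sigma_cond"]^2
    s0 <- m; s1 <- sum(t); s2 <- sum(t * t)
    Sy <- sum(y); Syt <- sum(y * t)
    b1off <- th[, "beta1"]
    p11 <- s0 / sw2 + lam^2 / sc2
    p12 <- s1 / sw2 - lam / sc2
    p22 <- s2 / sw2 + 1 / sc2
    h1 <- (Sy - b1off * s1) / sw2 + lam^2 * abar / sc2
    h2 <- (Syt - b1off * s2) / sw2 - lam * abar / sc2
    return(.mvn2_sample(p11, p12, p22, h1, h2, rnorm(K), rnorm(K)))
  }

  d <- model$d
  # population-level curve (no random effects), per draw
  A0 <- th[, "beta0"] + zoff[, 1L]
  B0 <- th[, "beta1"] + zoff[, 2L]
  C0 <- if (d == 3L) th[, "beta2"] + zoff[, 3L] else rep(0, K)

  sds0 <- th[, "sigma0"]; sds1 <- th[, "sigma1"]
  if (d == 2L) {
    Si <- .inv2(sds0^2, th[, "rho01"] * sds0 * sds1, sds1^2)
  } else {
    sds2 <- th[, "sigma2"]
    Si <- .inv3(sds0^2, th[, "rho01"] * sds0 * sds1,
                th[, "rho02"] * sds0 * sds2, sds1^2,
                th[, "rho12"] * sds1 * sds2, sds2^2)
  }

  gaussian <- model$error_family != "student_t"
  if (gaussian) {
    s0 <- m; s1 <- sum(t); s2 <- sum(t^2)
    s3 <- sum(t^3); s4 <- sum(t^4)
    Sy <- sum(y); Syt <- sum(y * t); Syt2 <- sum(y * t^2)
    h1 <- (Sy - s0 * A0 - s1 * B0 - s2 * C0) / sw2
    h2 <- (Syt - s1 * A0 - s2 * B0 - s3 * C0) / sw2
    if (d == 2L) {
      return(.mvn2_sample(Si$i11 + s0 / sw2, Si$i12 + s1 / sw2,
                          Si$i22 + s2 / sw2, h1, h2, rnorm(K), rnorm(K)))
    }
    h3 <- (Syt2 - s2 * A0 - s3 * B0 - s4 * C0) / sw2
    return(.mvn3_sample(Si$i11 + s0 / sw2, Si$i12 + s1 / sw2,
                        Si$i13 + s2 / sw2, Si$i22 + s2 / sw2,
                        Si$i23 + s3 / sw2, Si$i33 + s4 / sw2,
                        h1, h2, h3, rnorm(K), rnorm(K), rnorm(K)))
  }

  # Student-t errors: inner Gibbs on the scale-mixture weights
  nu <- th[, "nu"]
  Y <- matrix(y, K, m, byrow = TRUE)
  Tm <- matrix(t, K, m, byrow = TRUE)
  T2 <- Tm * Tm
  R0 <- Y - A0 - B0 * Tm - C0 * T2 # residual to the population curve
  b <- matrix(0, K, d)
  for (step in seq_len(inner_iter)) {
    lev_b <- b[, 1L] + b[, 2L] * Tm + if (d == 3L) b[, 3L] * T2 else 0
    resid <- R0 - lev_b
    lamw <- matrix(
      rgamma(K * m, (nu + 1) / 2, rate = (nu + resid^2 / sw2) / 2),
      K, m)
    s0 <- rowSums(lamw); s1 <- rowSums(lamw * Tm)
    s2 <- rowSums(lamw * T2)
    h1 <- rowSums(lamw * R0) / sw2
    h2 <- rowSums(lamw * R0 * Tm) / sw2
    if (d == 2L) {
      b <- .mvn2_sample(Si$i11 + s0 / sw2, Si$i12 + s1 / sw2,
                        Si$i22 + s2 / sw2, h1, h2, rnorm(K), rnorm(K))
    } else {
      s3 <- rowSums(lamw * Tm * T2); s4 <- rowSums(lamw * T2 * T2)
      h3 <- rowSums(lamw * R0 * T2) / sw2
      b <- .mvn3_sample(Si$i11 + s0 / sw2, Si$i12 + s1 / sw2,
                        Si$i13 + s2 / sw2, Si$i22 + s2 / sw2,
                        Si$i23 + s3 / sw2, Si$i33 + s4 / sw2,
                        h1, h2, h3, rnorm(K), rnorm(K), rnorm(K))
    }
  }
  b
}

#' @export
print.aaa_indpost <- function(x, ...) {
  cat("aaa_indpost:", x$n_draws, "draws,", x$trend, "trend\n")
  qs <- apply(x$coef[, 1:2], 2, quantile, c(0.5, 0.025, 0.975))
  cat(sprintf("level at t=0: %.1f (%.1f, %.1f) mm\n",
              qs[1, 1], qs[2, 1], qs[3, 1]))
  cat(sprintf("linear growth coefficient: %.2f (%.2f, %.2f) mm/year\n",
              qs[1, 2], qs[2, 2], qs[3, 2]))
  invisible(x)
}
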