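#' Fit a hierarchical growth model by blocked Gibbs sampling
#'
#' Draws from the joint posterior of the population parameters and the
#' subject random effects with conjugate blocked updates: multivariate
#' normal for the fixed effects and for each subject's random effects,
#' inverse gamma for the residual variance, inverse Wishart for the
#' random-effect covariance.  Student-t errors use per-observation
#' scale-mixture augmentation with the degrees of freedom updated by a
#' gridded Gibbs step on its uniform support; left-censored records are
#' handled by truncated-normal data augmentation; the independent-intercept
#' model updates each intercept individually under its uniform prior and
#' the slope-on-intercept coefficient by its truncated-normal conditional.
#'
#' All sub-steps are driven by `seed`, so runs are bit-reproducible.
#'
#' @param cohort an [aaa_cohort].
#' @param model an [model_spec()].
#' @param prior an [prior_spec()].
#' @param chains number of independent chains (at least 2 if convergence
#'   diagnostics are wanted).
#' @param iter iterations per chain.
#' @param burnin iterations discarded from the start of each chain.
#' @param seed integer seed.
#' @param keep_b keep the per-subject random-effect draws (needed for
#'   in-sample individual prediction; memory grows as draws x subjects).
#' @param nu_grid number of grid points for the degrees-of-freedom update.
#' @param fix_b if `TRUE`, random effects are fixed at zero and the
#'   covariance is not updated (used to validate the fixed-effect
#'   conditional against the closed-form normal-regression posterior).
#' @param fix_sigma_w optional fixed residual SD (same validation purpose).
#' @return an object of class `aaa_fit` with elements `theta` (matrix of
#'   draws, one named column per population parameter), `chain`
#'   (chain index per draw), `ll` (conditional log-likelihood per draw),
#'   `b` (draws x subjects x effect-dimension array, if kept), `b_mean`,
#'   `subject_ids`, `model`, `prior` and the MCMC settings.
#' @seealso [rhat()], [dic()], [individual_posterior()]
#' @export
fit_growth <- function(cohort, model = model_spec(), prior = prior_spec(),
                       chains = 2L, iter = 2000L, burnin = 500L, seed = 1L,
                       keep_b = TRUE, nu_grid = 400L,
                       fix_b = FALSE, fix_sigma_w = NULL) {
  stopifnot(inherits(cohort, "aaa_cohort"), inherits(model, "aaa_model"),
            inherits(prior, "aaa_prior"), iter > burnin, chains >= 1L)
  dat <- .fit_data(cohort, model)
  t0 <- proc.time()[["elapsed"]]
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(.substream(seed, 900000L + ch))
    runs[[ch]] <- if (model$intercept_model == "independent") {
      .gibbs_l2(dat, prior, iter, burnin, keep_b)
    } else {
      .gibbs_shared(dat, model, prior, iter, burnin, keep_b,
                    nu_grid, fix_b, fix_sigma_w)
    }
  }
  theta <- do.call(rbind, lapply(runs, `[[`, "theta"))
  chain <- rep(seq_len(chains), each = iter - burnin)
  ll <- unlist(lapply(runs, `[[`, "ll"), use.names = FALSE)
  b <- NULL
  if (keep_b) {
    b <- array(NA_real_, c(nrow(theta), dat$n,
                           dim(runs[[1]]$b)[3]))
    off <- 0L
    for (ch in seq_len(chains)) {
      nk <- dim(runs[[ch]]$b)[1]
      b[off + seq_len(nk), , ] <- runs[[ch]]$b
      off <- off + nk
    }
  }
  b_mean <- Reduce(`+`, lapply(runs, `[[`, "b_mean")) / chains
  structure(
    list(theta = theta, chain = chain, ll = ll, b = b, b_mean = b_mean,
         subject_ids = dat$ids, model = model, prior = prior,
         mcmc = list(chains = chains, iter = iter, burnin = burnin,
                     seed = seed),
         data_info = list(n = dat$n, N = dat$N,
                          n_censored = sum(dat$is_cens)),
         runtime = proc.time()[["elapsed"]] - t0),
    class = "aaa_fit"
  )
}

#' @export
print.aaa_fit <- function(x, ...) {
  cat("aaa_fit:", x$model$trend, "trend,",
      x$model$intercept_model, "intercepts,",
      x$model$error_family, "errors,",
      "censoring", x$model$censoring, "\n")
  cat(sprintf("%d subjects, %d measurements (%d censored)\n",
              x$data_info$n, x$data_info$N, x$data_info$n_censored))
  cat(sprintf("%d chains x %d iterations (%d burn-in), %.1f s\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$burnin, x$runtime))
  print(round(summary(x), 3))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object an `aaa_fit`.
#' @param probs quantiles to report.
#' @param ... unused.
#' @return matrix with posterior median, SD and quantiles per parameter.
#' @export
summary.aaa_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  th <- object$theta
  out <- cbind(median = apply(th, 2, median),
               sd = apply(th, 2, sd),
               t(apply(th, 2, quantile, probs = probs)))
  out
}

# ---- shared-normal sampler (L1 / Q1 / covariates / L1-T / censored) ------

.gibbs_shared <- function(dat, model, prior, iter, burnin, keep_b,
                          nu_grid, fix_b, fix_sigma_w) {
  d <- dat$d
  q <- dat$q
  n <- dat$n
  N <- dat$N
  t <- dat$t
  id <- dat$id
  X <- dat$X
  D <- if (q > 0L) cbind(dat$X, dat$W) else dat$X
  p <- ncol(D)
  is_cens <- dat$is_cens
  n_cens <- sum(is_cens)
  is_t <- model$error_family == "student_t"

  P0 <- diag(1 / prior$tau_fixed^2, p)
  a0 <- prior$sigma_w_shape
  r0 <- prior$sigma_w_rate
  S0 <- if (is.null(prior$wishart_scale)) diag(d) else prior$wishart_scale
  df0 <- prior$wishart_df_offset + d

  if (is_t) {
    lgrid <- seq(log(prior$df_bounds[1]), log(prior$df_bounds[2]),
                 length.out = nu_grid)
    lstep <- lgrid[2] - lgrid[1]
    nug <- exp(lgrid)
  }

  # initial values
  ycur <- dat$y
  if (n_cens) ycur[is_cens] <- dat$bound[is_cens] - 1
  thf <- qr.solve(crossprod(D) + diag(1e-8, p), crossprod(D, ycur))
  b <- matrix(0, n, d)
  Sigma <- diag(c(25, 1, 0.01)[seq_len(d)])
  sw2 <- if (is.null(fix_sigma_w)) {
    max(mean((ycur - D %*% thf)^2) / 2, 1e-4)
  } else fix_sigma_w^2
  lam <- rep(1, N)
  nu <- 10

  n_keep <- iter - burnin
  pn <- c(paste0("beta", seq_len(d) - 1L),
          if (q > 0L) colnames(dat$W),
          "sigma_w",
          paste0("sigma", seq_len(d) - 1L),
          if (d == 2L) "rho01" else c("rho01", "rho02", "rho12"),
          if (is_t) "nu")
  theta <- matrix(NA_real_, n_keep, length(pn),
                  dimnames = list(NULL, pn))
  ll <- numeric(n_keep)
  barr <- if (keep_b) array(NA_real_, c(n_keep, n, d)) else NULL
  b_sum <- matrix(0, n, d)

  for (it in seq_len(iter)) {
    fitted_b <- rowSums(X * b[id, , drop = FALSE])
    mu_fix <- drop(D %*% thf)

    # data augmentation for left-censored records
    if (n_cens) {
      mu_c <- (mu_fix + fitted_b)[is_cens]
      ycur[is_cens] <- .rtnorm_upper(n_cens, mu_c, sqrt(sw2),
                                     dat$bound[is_cens])
    }

    # scale-mixture weights for t errors
    if (is_t) {
      resid <- ycur - mu_fix - fitted_b
      lam <- rgamma(N, (nu + 1) / 2, rate = (nu + resid^2 / sw2) / 2)
    }

    # fixed effects (beta, gamma) jointly
    target <- ycur - fitted_b
    A <- crossprod(D, D * lam) / sw2 + P0
    h <- crossprod(D, lam * target) / sw2
    R <- chol(A)
    thf <- drop(backsolve(R, backsolve(R, h, transpose = TRUE)) +
                  backsolve(R, rnorm(p)))
    mu_fix <- drop(D %*% thf)

    # subject random effects
    if (!fix_b) {
      r <- ycur - mu_fix
      if (d == 2L) {
        M <- rowsum(cbind(lam, lam * t, lam * t * t,
                          lam * r, lam * r * t), id)
        Si <- .inv2(Sigma[1, 1], Sigma[1, 2], Sigma[2, 2])
        b <- .mvn2_sample(Si$i11 + M[, 1] / sw2,
                          Si$i12 + M[, 2] / sw2,
                          Si$i22 + M[, 3] / sw2,
                          M[, 4] / sw2, M[, 5] / sw2,
                          rnorm(n), rnorm(n))
      } else {
        t2 <- t * t
        M <- rowsum(cbind(lam, lam * t, lam * t2, lam * t * t2,
                          lam * t2 * t2,
                          lam * r, lam * r * t, lam * r * t2), id)
        Si <- .inv3(Sigma[1, 1], Sigma[1, 2], Sigma[1, 3],
                    Sigma[2, 2], Sigma[2, 3], Sigma[3, 3])
        b <- .mvn3_sample(Si$i11 + M[, 1] / sw2,
                          Si$i12 + M[, 2] / sw2,
                          Si$i13 + M[, 3] / sw2,
                          Si$i22 + M[, 3] / sw2,
                          Si$i23 + M[, 4] / sw2,
                          Si$i33 + M[, 5] / sw2,
                          M[, 6] / sw2, M[, 7] / sw2, M[, 8] / sw2,
                          rnorm(n), rnorm(n), rnorm(n))
      }
      fitted_b <- rowSums(X * b[id, , drop = FALSE])
    }

    # residual variance
    resid <- ycur - mu_fix - fitted_b
    if (is.null(fix_sigma_w)) {
      sw2 <- 1 / rgamma(1, a0 + N / 2, rate = r0 + sum(lam * resid^2) / 2)
    }

    # random-effect covariance
    if (!fix_b) {
      Sigma <- .rinvwishart(df0 + n, S0 + crossprod(b))

      # translation ("sweep") move between beta and the random-effect
      # mean: the likelihood depends only on beta + b_i, so delta has a
      # conjugate normal conditional; this removes the slow random walk
      # between the two blocks
      Sinv <- solve(Sigma)
      Pd <- n * Sinv + diag(1 / prior$tau_fixed^2, d)
      hd <- Sinv %*% colSums(b) - thf[seq_len(d)] / prior$tau_fixed^2
      Rd <- chol(Pd)
      delta <- drop(backsolve(Rd, backsolve(Rd, hd, transpose = TRUE)) +
                      backsolve(Rd, rnorm(d)))
      thf[seq_len(d)] <- thf[seq_len(d)] + delta
      b <- b - rep(delta, each = n)
      mu_fix <- drop(D %*% thf)
      fitted_b <- rowSums(X * b[id, , drop = FALSE])
    }

    # degrees of freedom (gridded Gibbs on log scale)
    if (is_t) {
      slog <- sum(log(lam))
      ssum <- sum(lam)
      lp <- N * (nug / 2 * log(nug / 2) - lgamma(nug / 2)) +
        (nug / 2 - 1) * slog - nug / 2 * ssum
      lp <- lp - max(lp)
      k <- sample.int(length(nug), 1L, prob = exp(lp))
      nu <- exp(lgrid[k] + runif(1, -lstep / 2, lstep / 2))
      nu <- min(max(nu, prior$df_bounds[1]), prior$df_bounds[2])
    }

    if (it > burnin) {
      k <- it - burnin
      sds <- sqrt(diag(Sigma))
      rhos <- if (d == 2L) {
        Sigma[1, 2] / (sds[1] * sds[2])
      } else {
        c(Sigma[1, 2] / (sds[1] * sds[2]),
          Sigma[1, 3] / (sds[1] * sds[3]),
          Sigma[2, 3] / (sds[2] * sds[3]))
      }
      theta[k, ] <- c(thf, sqrt(sw2), sds, rhos, if (is_t) nu)
      ll[k] <- .loglik_state(dat, model, mu_fix + fitted_b, sw2, nu)
      if (keep_b) barr[k, , ] <- b
      b_sum <- b_sum + b
    }
  }
  list(theta = theta, ll = ll, b = barr, b_mean = b_sum / n_keep)
}

# Conditional log-likelihood of the current state: observed rows use the
# error density, censored rows the log CDF at the bound.
.loglik_state <- function(dat, model, mu, sw2, nu = NULL) {
  sw <- sqrt(sw2)
  obs <- !dat$is_cens
  resid <- dat$y[obs] - mu[obs]
  ll <- if (model$error_family == "student_t") {
    sum(dt(resid / sw, df = nu, log = TRUE)) - sum(obs) * log(sw)
  } else {
    sum(dnorm(resid, 0, sw, log = TRUE))
  }
  if (any(dat$is_cens)) {
    z <- (dat$bound[dat$is_cens] - mu[dat$is_cens]) / sw
    ll <- ll + sum(pnorm(z, log.p = TRUE))
  }
  ll
}

# ---- independent-intercept sampler (L2) ----------------------------------

.gibbs_l2 <- function(dat, prior, iter, burnin, keep_b) {
  n <- dat$n
  N <- dat$N
  t <- dat$t
  id <- dat$id
  y <- dat$y
  a0 <- prior$sigma_w_shape
  r0 <- prior$sigma_w_rate
  lb <- prior$lambda_bounds
  ib <- prior$intercept_bounds
  tau2 <- prior$tau_fixed^2

  cnt <- as.vector(rowsum(rep(1, N), id))
  st2 <- as.vector(rowsum(t * t, id))

  alpha <- as.vector(rowsum(y, id)) / cnt
  b1 <- rep(0, n)
  beta1 <- 2
  lambda <- 0.3
  sc2 <- 1
  sw2 <- 4

  n_keep <- iter - burnin
  pn <- c("beta0", "beta1", "sigma_w", "sigma0", "sigma1", "rho01",
          "lambda", "sigma_cond")
  theta <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  ll <- numeric(n_keep)
  barr <- if (keep_b) array(NA_real_, c(n_keep, n, 2L)) else NULL
  b_sum <- matrix(0, n, 2L)

  model_g <- list(error_family = "gaussian") # for .loglik_state

  for (it in seq_len(iter)) {
    abar <- mean(alpha)
    # independent intercepts, U(ib) prior plus the slope-model term
    slope <- beta1 + b1
    hy <- as.vector(rowsum(y - slope[id] * t, id))
    prec <- cnt / sw2 + lambda^2 / sc2
    h <- hy / sw2 + lambda * (b1 + lambda * abar) / sc2
    alpha <- .rtnorm_range(n, h / prec, 1 / sqrt(prec), ib[1], ib[2])
    abar <- mean(alpha)
    cdev <- alpha - abar

    # slope random effects, conditionally gaussian on the intercepts
    ht <- as.vector(rowsum(t * (y - alpha[id] - beta1 * t), id))
    prec <- st2 / sw2 + 1 / sc2
    h <- ht / sw2 + lambda * cdev / sc2
    b1 <- h / prec + rnorm(n) / sqrt(prec)

    # population mean slope
    prec <- sum(st2) / sw2 + 1 / tau2
    h <- sum(t * (y - alpha[id] - b1[id] * t)) / sw2
    beta1 <- h / prec + rnorm(1) / sqrt(prec)

    # slope-on-intercept coefficient, U(lb) prior
    sc <- sum(cdev^2)
    lambda <- .rtnorm_range(1, sum(cdev * b1) / sc, sqrt(sc2 / sc),
                            lb[1], lb[2])

    # conditional slope variance
    sc2 <- 1 / rgamma(1, a0 + n / 2,
                      rate = r0 + sum((b1 - lambda * cdev)^2) / 2)

    # translation move between beta1 and the slope-effect mean (the
    # likelihood depends only on beta1 + b1_i)
    pd <- n / sc2 + 1 / tau2
    hd <- sum(b1 - lambda * cdev) / sc2 - beta1 / tau2
    delta <- hd / pd + rnorm(1) / sqrt(pd)
    beta1 <- beta1 + delta
    b1 <- b1 - delta

    # residual variance
    resid <- y - alpha[id] - (beta1 + b1[id]) * t
    sw2 <- 1 / rgamma(1, a0 + N / 2, rate = r0 + sum(resid^2) / 2)

    if (it > burnin) {
      k <- it - burnin
      theta[k, ] <- c(abar, beta1, sqrt(sw2), sd(alpha), sd(b1),
                      cor(alpha, b1), lambda, sqrt(sc2))
      ll[k] <- .loglik_state(dat, model_g, y - resid, sw2)
      if (keep_b) {
        barr[k, , 1L] <- alpha
        barr[k, , 2L] <- b1
      }
      b_sum <- b_sum + cbind(alpha, b1)
    }
  }
  list(theta = theta, ll = ll, b = barr, b_mean = b_sum / n_keep)
}
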