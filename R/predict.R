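#' Posterior distribution of an individual's growth rate
#'
#' The growth rate at time `t` is the derivative of the individual's
#' underlying growth curve: constant for the linear model, and
#' `B + 2 C t` for the quadratic.
#'
#' @param ind an [individual_posterior()].
#' @param t time (years) at which the rate is evaluated; required for a
#'   quadratic model.
#' @return an `aaa_prediction` with draws in mm/year.
#' @export
growth_rate <- function(ind, t = NULL) {
  stopifnot(inherits(ind, "aaa_indpost"))
  if (is.null(t)) {
    if (ind$trend == "quadratic") {
      stop("t must be given for a quadratic model (the rate varies in ",
           "time)", call. = FALSE)
    }
    t <- 0
  }
  draws <- ind$coef[, "B"] + 2 * ind$coef[, "C"] * t
  .prediction(draws, "growth rate (mm/year)")
}

#' Time for the underlying curve to reach a threshold
#'
#' For each posterior draw, the waiting time `W` from `t` until the
#' individual's underlying (error-free) growth curve first reaches the
#' threshold `alpha`, on the extended non-negative real line:
#'
#' * `W = 0` when the underlying level at `t` is already at or above
#'   `alpha`;
#' * linear curve: `W = (alpha - level(t)) / slope` when the slope is
#'   positive, else `W = Inf` (the threshold is never crossed);
#' * quadratic curve: the smallest root of `level(u) = alpha` exceeding
#'   `t`, measured from `t`; `W = Inf` when there is no real root or both
#'   roots precede `t`.
#'
#' Roots use the numerically stable quadratic formula; draws with a
#' negligible curvature coefficient (|C| below `tiny`) fall back to the
#' linear rule.  Quantiles are computed on the extended line with `Inf`
#' ordered above all reals (inverse-ECDF, no interpolation); the
#' probability masses at 0 and at infinity are reported alongside.
#'
#' @param ind an [individual_posterior()].
#' @param t prediction time in years.
#' @param alpha threshold in mm (55 mm is the surgical referral level).
#' @param tiny curvature magnitude under which a draw is treated as linear.
#' @return an `aaa_prediction` with fields `p_zero` and `p_inf`.
#' @export
time_to_threshold <- function(ind, t = 0, alpha = 55, tiny = 1e-12) {
  stopifnot(inherits(ind, "aaa_indpost"), alpha > 0, t >= 0)
  A <- ind$coef[, "A"]; B <- ind$coef[, "B"]; C <- ind$coef[, "C"]
  K <- length(A)
  level_t <- A + B * t + C * t * t
  W <- rep(Inf, K)
  zero <- level_t >= alpha
  W[zero] <- 0

  lin <- !zero & abs(C) < tiny
  Wl <- (alpha - level_t[lin]) / B[lin]
  Wl[B[lin] <= 0] <- Inf
  W[lin] <- Wl

  qd <- !zero & !lin
  if (any(qd)) {
    a <- C[qd]; bb <- B[qd]; cc <- A[qd] - alpha
    disc <- bb * bb - 4 * a * cc
    r1 <- rep(NA_real_, sum(qd)); r2 <- r1
    real <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    bz <- real & bb == 0
    r1[bz] <- -sq[bz] / (2 * a[bz])
    r2[bz] <- sq[bz] / (2 * a[bz])
    nz <- real & bb != 0
    qq <- -(bb[nz] + sign(bb[nz]) * sq[nz]) / 2
    r1[nz] <- qq / a[nz]
    r2[nz] <- cc[nz] / qq
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    first <- ifelse(!real, Inf,
                    ifelse(lo > t, lo, ifelse(hi > t, hi, Inf)))
    W[qd] <- pmax(first - t, 0)
  }
  out <- .prediction(W, sprintf("years to reach %g mm from t=%g", alpha, t),
                     extended = TRUE)
  out$p_zero <- mean(W == 0)
  out$p_inf <- mean(is.infinite(W))
  out
}

#' Posterior predictive of a future measurement
#'
#' For each draw, the underlying level at time `t + s` plus (for
#' `type = "observed"`) a fresh measurement error from the fitted error
#' family — the posterior predictive distribution of what an ultrasound at
#' `t + s` would record.  `type = "underlying"` returns the error-free
#' level instead.
#'
#' @param ind an [individual_posterior()].
#' @param t current time (years).
#' @param s horizon ahead of `t` (years, non-negative).
#' @param type `"observed"` or `"underlying"`.
#' @param seed optional seed for the fresh error draws.
#' @return an `aaa_prediction` with draws in mm.
#' @export
predict_measurement <- function(ind, t = 0, s = 0,
                                type = c("observed", "underlying"),
                                seed = NULL) {
  stopifnot(inherits(ind, "aaa_indpost"), s >= 0)
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  u <- t + s
  mu <- ind$coef[, "A"] + ind$coef[, "B"] * u + ind$coef[, "C"] * u * u
  if (type == "observed") {
    K <- length(mu)
    err <- if (ind$error_family == "student_t") {
      ind$sigma_w * rt(K, df = ind$nu)
    } else {
      rnorm(K, 0, ind$sigma_w)
    }
    mu <- mu + err
  }
  .prediction(mu, sprintf("%s diameter at t+s=%g (mm)", type, u))
}

#' Probability that a future measurement exceeds a threshold
#'
#' The tail area of the posterior predictive distribution above `alpha` at
#' horizon `s`, computed in Rao–Blackwellised form: for each draw the
#' closed-form tail probability of the error family around the underlying
#' level — `1 - F((alpha - level)/sigma_w)` with `F` standard normal or
#' Student-t — averaged over draws.  This is the planning criterion for
#' monitoring intervals.
#'
#' @param ind an [individual_posterior()].
#' @param t current time (years).
#' @param s horizon(s) in years; may be a vector.
#' @param alpha threshold in mm.
#' @return numeric vector of probabilities, one per element of `s`, with
#'   the per-draw tail probabilities in attribute `"per_draw"` (draws x
#'   horizons).
#' @export
exceedance_prob <- function(ind, t = 0, s = 1, alpha = 55) {
  stopifnot(inherits(ind, "aaa_indpost"), all(s >= 0))
  u <- t + s
  mu <- outer(ind$coef[, "A"], rep(1, length(u))) +
    outer(ind$coef[, "B"], u) + outer(ind$coef[, "C"], u * u)
  z <- (alpha - mu) / ind$sigma_w
  tail <- if (ind$error_family == "student_t") {
    1 - pt(z, df = ind$nu)
  } else {
    1 - pnorm(z)
  }
  p <- colMeans(tail)
  names(p) <- paste0("s=", s)
  attr(p, "per_draw") <- tail
  p
}

# Common prediction container with extended-line-aware summaries.
.prediction <- function(draws, label, extended = FALSE) {
  q <- if (extended) {
    quantile(draws, c(0.5, 0.025, 0.975), type = 1, names = FALSE)
  } else {
    quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
  }
  structure(list(draws = draws, label = label,
                 median = q[1], lower = q[2], upper = q[3]),
            class = "aaa_prediction")
}

#' @export
print.aaa_prediction <- function(x, ...) {
  cat(sprintf("%s: %.3g (95%% interval %.3g, %.3g)\n",
              x$label, x$median, x$lower, x$upper))
  if (!is.null(x$p_zero)) {
    cat(sprintf("P(already reached) = %.3f   P(never reached) = %.3f\n",
                x$p_zero, x$p_inf))
  }
  invisible(x)
}
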