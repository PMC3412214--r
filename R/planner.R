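#' Recommend a rescan interval for a given baseline diameter
#'
#' Finds the longest wait `s` such that the probability of the *observed*
#' diameter being at or above the threshold at the next scan stays within
#' the chosen risk limit: the largest grid point on `[0, max_horizon]`
#' with `exceedance_prob(s) <= risk_limit`, refined by bisection to a
#' tolerance of `grid_step / 10`.  When even an immediate remeasurement
#' (`s = 0`) exceeds the limit — possible for large baselines, since
#' measurement error alone can push the observed value over the threshold
#' — the recommendation is 0 years with the `already_exceeded` flag set.
#'
#' @param population an `aaa_fit` of the population model.
#' @param baseline baseline diameter in mm (a single screening measurement
#'   at `t = 0`), or an [individual_posterior()] for a full history.
#' @param alpha referral threshold in mm.
#' @param risk_limit acceptable probability of exceeding `alpha` at the
#'   next scan (in (0,1)).
#' @param max_horizon longest interval considered, years.
#' @param grid_step search grid resolution, years.
#' @param type predictive used for the criterion: `"observed"`
#'   (error-inclusive, the default, matching how screening programmes act
#'   on measured diameters) or `"underlying"`.
#' @param covariates,seed passed to [individual_posterior()] when
#'   `baseline` is a number.
#' @return interval in years (possibly 0), with attributes
#'   `already_exceeded` and `prob_at_interval`.
#' @export
recommend_interval <- function(population, baseline, alpha = 55,
                               risk_limit = 0.01, max_horizon = 10,
                               grid_step = 0.25,
                               type = c("observed", "underlying"),
                               covariates = NULL, seed = NULL) {
  type <- match.arg(type)
  stopifnot(risk_limit > 0, risk_limit < 1, grid_step > 0, max_horizon > 0)
  ind <- if (inherits(baseline, "aaa_indpost")) baseline else {
    individual_posterior(population, times = 0, values = baseline,
                         covariates = covariates, seed = seed)
  }
  pfun <- if (type == "observed") {
    function(s) unname(exceedance_prob(ind, t = 0, s = s, alpha = alpha))
  } else {
    # threshold on the error-free underlying level
    function(s) {
      u <- outer(ind$coef[, "A"], rep(1, length(s))) +
        outer(ind$coef[, "B"], s) + outer(ind$coef[, "C"], s * s)
      unname(colMeans(u >= alpha))
    }
  }
  grid <- seq(0, max_horizon, by = grid_step)
  if (grid[length(grid)] < max_horizon) grid <- c(grid, max_horizon)
  p <- pfun(grid)
  if (p[1] > risk_limit) {
    return(structure(0, already_exceeded = TRUE, prob_at_interval = p[1]))
  }
  ok <- which(p <= risk_limit)
  k <- max(ok)
  if (k == length(grid)) {
    return(structure(max_horizon, already_exceeded = FALSE,
                     prob_at_interval = p[k]))
  }
  lo <- grid[k]; hi <- grid[k + 1L]
  tol <- grid_step / 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pfun(mid) <= risk_limit) lo <- mid else hi <- mid
  }
  structure(lo, already_exceeded = FALSE, prob_at_interval = pfun(lo))
}

#' Rescan-interval policy over a grid of baselines and risk limits
#'
#' Tabulates [recommend_interval()] over baseline diameters and risk
#' limits — the policy table behind "probability of exceeding the referral
#' threshold at rescreening" planning curves.  Intervals are
#' non-increasing in baseline diameter and non-decreasing in the risk
#' limit (up to search tolerance).
#'
#' @param population an `aaa_fit`.
#' @param baselines baseline diameters (mm).
#' @param risk_limits probability limits.
#' @param ... passed to [recommend_interval()].
#' @param seed seed used for the per-baseline cut posteriors.
#' @return data frame of class `aaa_policy` with columns `baseline`,
#'   `risk_limit`, `interval`, `prob` (the exceedance probability at the
#'   recommended interval) and `already_exceeded`.
#' @export
policy_curve <- function(population, baselines = seq(30, 54, by = 2),
                         risk_limits = c(0.01, 0.05, 0.10), seed = 1,
                         ...) {
  rows <- list()
  for (bl in baselines) {
    ind <- individual_posterior(population, times = 0, values = bl,
                                seed = .substream(seed, round(bl * 100)))
    for (rl in risk_limits) {
      iv <- recommend_interval(population, ind, risk_limit = rl, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        baseline = bl, risk_limit = rl, interval = as.numeric(iv),
        prob = attr(iv, "prob_at_interval"),
        already_exceeded = isTRUE(attr(iv, "already_exceeded")))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aaa_policy", "data.frame")
  out
}

#' Plot a rescan-interval policy table
#'
#' One curve of recommended interval against baseline diameter per risk
#' limit.
#'
#' @param x an `aaa_policy` from [policy_curve()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.aaa_policy <- function(x, ...) {
  wide <- reshape(as.data.frame(x)[c("baseline", "risk_limit", "interval")],
                  idvar = "baseline", timevar = "risk_limit",
                  direction = "wide")
  graphics::matplot(wide$baseline, wide[-1], type = "l", lty = 1:3,
                    col = 1,
                    xlab = "baseline diameter (mm)",
                    ylab = "recommended rescan interval (years)", ...)
  graphics::legend("topright", lty = 1:3,
                   legend = paste0(100 * sort(unique(x$risk_limit)), "%"))
  invisible(x)
}
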