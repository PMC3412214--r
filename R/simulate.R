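#' Ground-truth parameters for the synthetic cohort generator
#'
#' Describes the generating hierarchical growth model: population intercept /
#' slope (/ curvature), the random-effect covariance (SDs plus correlations),
#' the residual scale, the measurement-error family, optional baseline
#' covariate effects and the law of the baseline random intercept.  Defaults
#' are the fitted population values for a screened AAA cohort (intercept
#' 37.5 mm, growth 2.19 mm/year, SDs 7.12 and 1.74, correlation 0.51,
#' residual SD 3.12 mm).
#'
#' @param beta fixed-effect vector: `(intercept, slope)` for a linear truth
#'   or `(intercept, slope, curvature)` for a quadratic one.
#' @param sds random-effect standard deviations, same length as `beta`.
#' @param rhos random-effect correlations: `rho01` for linear;
#'   `(rho01, rho02, rho12)` for quadratic.
#' @param sigma_w residual (within-subject measurement error) SD in mm.
#' @param error_family `"gaussian"` or `"student_t"` measurement errors; in
#'   the latter case errors are `sigma_w` times a standard t with `df`
#'   degrees of freedom.
#' @param df degrees of freedom for `error_family = "student_t"` (must
#'   exceed 2).
#' @param gamma optional covariate effects: a named list, one element per
#'   covariate, each a numeric vector of per-component effects (intercept,
#'   slope\[, curvature\]) matching `length(beta)`.
#' @param baseline_law `"normal"` (random intercept multivariate normal with
#'   the slope) or `"skewed"`: the baseline diameter level
#'   `beta[1] + b_0i` follows a shifted gamma on \[30, 55) mm — mimicking
#'   the right-skewed histogram of screen-detected diameters — and the
#'   slope effect follows its usual normal conditional given `b_0i`.  Only
#'   available for linear truths.
#' @param skew_shape,skew_scale shape and scale of the shifted-gamma
#'   baseline law; the defaults give a truncated mean of about 37.5 mm and
#'   SD of about 7 mm on \[30, 55).
#' @return an object of class `aaa_truth`.
#' @export
truth_params <- function(beta = c(37.5, 2.19),
                         sds = c(7.12, 1.74),
                         rhos = 0.51,
                         sigma_w = 3.12,
                         error_family = c("gaussian", "student_t"),
                         df = 4,
                         gamma = NULL,
                         baseline_law = c("normal", "skewed"),
                         skew_shape = 0.56, skew_scale = 35.8) {
  error_family <- match.arg(error_family)
  baseline_law <- match.arg(baseline_law)
  d <- length(beta)
  stopifnot(d %in% c(2L, 3L), length(sds) == d,
            length(rhos) == if (d == 2L) 1L else 3L,
            sigma_w >= 0, all(sds >= 0))
  if (error_family == "student_t" && df <= 2) {
    stop("student_t errors require df > 2", call. = FALSE)
  }
  if (baseline_law == "skewed" && d != 2L) {
    stop("skewed baseline law is defined for linear truths only",
         call. = FALSE)
  }
  if (!is.null(gamma)) {
    stopifnot(is.list(gamma), !is.null(names(gamma)),
              all(vapply(gamma, length, 1L) == d))
  }
  Sigma <- if (all(sds > 0)) .make_sigma(sds, rhos) else {
    diag(sds^2, d) # degenerate components allowed for testing
  }
  structure(list(beta = as.numeric(beta), gamma = gamma, sds = sds,
                 rhos = rhos, Sigma = Sigma, sigma_w = sigma_w,
                 error_family = error_family, df = df,
                 baseline_law = baseline_law,
                 skew_shape = skew_shape, skew_scale = skew_scale),
            class = "aaa_truth")
}

#' Scan schedule rule for the synthetic generator
#'
#' Next-scan intervals depend on the current observed diameter: by default
#' one year below 45 mm and 3 months (0.25 years) from 45 mm upwards,
#' following surveillance practice in screening programmes.  Appointments
#' are jittered and may be missed; a missed appointment is skipped, not
#' rescheduled — the following appointment is booked from the missed date.
#'
#' @param band_breaks increasing diameter cut points (mm) separating
#'   interval bands.
#' @param intervals scan intervals (years), one more than `band_breaks`:
#'   `intervals[k]` applies to diameters in the k-th band.
#' @param attendance_prob probability a scheduled scan actually occurs.
#' @param jitter_sd SD (years) of Gaussian noise on appointment times.
#' @param min_gap smallest allowed gap between successive scans (years).
#' @return an object of class `aaa_schedule`.
#' @export
schedule_rule <- function(band_breaks = 45, intervals = c(1, 0.25),
                          attendance_prob = 0.82, jitter_sd = 0.08,
                          min_gap = 0.05) {
  stopifnot(length(intervals) == length(band_breaks) + 1L,
            all(intervals > 0), attendance_prob > 0, attendance_prob <= 1,
            jitter_sd >= 0, min_gap > 0)
  structure(list(band_breaks = band_breaks, intervals = intervals,
                 attendance_prob = attendance_prob, jitter_sd = jitter_sd,
                 min_gap = min_gap),
            class = "aaa_schedule")
}

#' Dropout rule for the synthetic generator
#'
#' Series terminate at the first of: elective surgery (observed diameter at
#' or over `surgery_threshold`, or observed growth of at least
#' `rapid_growth_trigger` mm between consecutive scans at most 1.25 years
#' apart), death, loss to follow-up (independent exponential hazards)
#' or the administrative horizon.  The hazards are calibrated defaults: the
#' study being emulated reports termination proportions, not mechanisms.
#'
#' @param surgery_threshold mm; observed value triggering surgery referral.
#' @param rapid_growth_trigger mm of observed growth between scans at most
#'   1.25 years apart that triggers surgery referral.
#' @param referral_prob probability that a referral-triggering scan leads
#'   to surgery; otherwise the patient is deemed unsuitable (permanently)
#'   and surveillance continues, as in the emulated programme.
#' @param death_rate,loss_rate per-year exponential hazards.
#' @param admin_horizon administrative censoring time in years.
#' @return an object of class `aaa_dropout`.
#' @export
dropout_rule <- function(surgery_threshold = 55, rapid_growth_trigger = 10,
                         referral_prob = 0.7,
                         death_rate = 0.045, loss_rate = 0.065,
                         admin_horizon = 11) {
  stopifnot(surgery_threshold > 0, rapid_growth_trigger > 0,
            referral_prob >= 0, referral_prob <= 1,
            death_rate >= 0, loss_rate >= 0, admin_horizon > 0)
  structure(list(surgery_threshold = surgery_threshold,
                 rapid_growth_trigger = rapid_growth_trigger,
                 referral_prob = referral_prob,
                 death_rate = death_rate, loss_rate = loss_rate,
                 admin_horizon = admin_horizon),
            class = "aaa_dropout")
}

#' Configuration for a synthetic screening cohort
#'
#' @param n_subjects number of followed-up subjects to generate.
#' @param truth an [truth_params()] object.
#' @param schedule an [schedule_rule()] object.
#' @param dropout a [dropout_rule()] object.
#' @param entry_filter how the first (screening) scan gates entry:
#'   `"observed"` rejects and redraws subjects whose observed first scan is
#'   outside \[30, 55) mm, emulating the screening study's inclusion rule;
#'   `"none"` keeps every simulated subject (simulation exactly from the
#'   model — use this for parameter-recovery experiments, since rejection
#'   on the observed baseline truncates the random-intercept law);
#'   `"censor"` turns sub-30 mm first scans into single left-censored
#'   records (bound 30 mm, no follow-up) and rejects first scans at or
#'   over 55 mm.
#' @param censor_population_n additional screening-population subjects whose
#'   first scan, when under 30 mm, is emitted as a left-censored record
#'   (those at or over 30 mm are discarded from this extra pool).  The
#'   emulated programme screened ~27000 men of whom ~25500 were below the
#'   30 mm aneurysm definition.
#' @param covariate_gen optional `function(n)` returning a data frame of
#'   `n` rows of baseline covariates (drawn with the generator's RNG
#'   substreams, so reproducible).
#' @param seed integer seed.  Each subject uses an independent substream
#'   derived from `seed`, so cohorts generated with a larger `n_subjects`
#'   share their first subjects with smaller runs.
#' @return an object of class `aaa_genconfig`.
#' @export
generator_config <- function(n_subjects = 1046, truth = truth_params(),
                             schedule = schedule_rule(),
                             dropout = dropout_rule(),
                             entry_filter = c("observed", "none", "censor"),
                             censor_population_n = 0,
                             covariate_gen = NULL, seed = 1) {
  entry_filter <- match.arg(entry_filter)
  stopifnot(n_subjects >= 1, inherits(truth, "aaa_truth"),
            inherits(schedule, "aaa_schedule"),
            inherits(dropout, "aaa_dropout"),
            censor_population_n >= 0)
  structure(list(n_subjects = as.integer(n_subjects), truth = truth,
                 schedule = schedule, dropout = dropout,
                 entry_filter = entry_filter,
                 censor_population_n = as.integer(censor_population_n),
                 covariate_gen = covariate_gen, seed = as.integer(seed)),
            class = "aaa_genconfig")
}

#' Draw subject-specific random effects from the generating truth
#'
#' Under the normal law, `b_i` is multivariate normal with the truth's
#' covariance.  Under the skewed baseline law the intercept effect is drawn
#' so that the baseline level `beta[1] + b_0i` follows a shifted gamma
#' truncated to \[30, 55) mm, and the slope effect follows its normal
#' conditional `b_1i | b_0i ~ N(rho*s1/s0 * b_0i, s1^2 (1 - rho^2))`.
#'
#' Uses R's current RNG stream.
#'
#' @param truth an [truth_params()] object.
#' @param n number of subjects to draw.
#' @return an `n` by `length(beta)` matrix of random effects.
#' @export
draw_subject_effects <- function(truth, n = 1L) {
  stopifnot(inherits(truth, "aaa_truth"))
  d <- length(truth$beta)
  if (truth$baseline_law == "skewed") {
    level <- .rgamma_trunc(n, truth$skew_shape, truth$skew_scale,
                           upper = 25) + 30
    b0 <- level - truth$beta[1]
    s0 <- truth$sds[1]; s1 <- truth$sds[2]; rho <- truth$rhos[1]
    b1 <- rho * s1 / s0 * b0 + rnorm(n, 0, s1 * sqrt(1 - rho^2))
    return(cbind(b0, b1, deparse.level = 0))
  }
  if (all(truth$sds == 0)) return(matrix(0, n, d))
  .rmvnorm(n, matrix(0, n, d), truth$Sigma)
}

# Gamma(shape, scale) truncated to [0, upper), by inverse CDF.
.rgamma_trunc <- function(n, shape, scale, upper) {
  pu <- pgamma(upper, shape = shape, scale = scale)
  qgamma(runif(n) * pu, shape = shape, scale = scale)
}

.draw_errors <- function(truth, n) {
  if (truth$error_family == "student_t") {
    truth$sigma_w * rt(n, df = truth$df)
  } else {
    rnorm(n, 0, truth$sigma_w)
  }
}

#' Simulate one subject's measurement series
#'
#' Generates scan times from the schedule rule (interval chosen by the last
#' observed diameter, with jitter and missed appointments), measurement
#' values from the growth curve implied by `truth` and the subject's random
#' effects, and terminates the series at the first of surgery referral,
#' death, loss to follow-up or the administrative horizon.  Uses R's
#' current RNG stream.
#'
#' @param truth,schedule,dropout generator components; see
#'   [truth_params()], [schedule_rule()], [dropout_rule()].
#' @param covariates optional named numeric vector of this subject's
#'   baseline covariates (must match `truth$gamma`).
#' @param subject_id identifier used in the returned data.
#' @param b optional random-effect vector; drawn from `truth` when `NULL`.
#' @return a list with elements `measurements` (data frame `time`, `value`),
#'   `termination`, and `b` (the random effects used).
#' @export
simulate_subject <- function(truth, schedule = schedule_rule(),
                             dropout = dropout_rule(), covariates = NULL,
                             subject_id = "s1", b = NULL) {
  stopifnot(inherits(truth, "aaa_truth"))
  d <- length(truth$beta)
  if (is.null(b)) b <- drop(draw_subject_effects(truth, 1L))
  coef <- truth$beta + b
  if (!is.null(truth$gamma)) {
    z <- covariates[names(truth$gamma)]
    if (anyNA(z)) stop("subject lacks covariates named in truth$gamma",
                       call. = FALSE)
    for (k in seq_along(truth$gamma)) {
      coef <- coef + truth$gamma[[k]] * z[[k]]
    }
  }
  level <- function(t) {
    if (d == 2L) coef[1] + coef[2] * t else
      coef[1] + coef[2] * t + coef[3] * t^2
  }
  t_death <- if (dropout$death_rate > 0) {
    rexp(1, dropout$death_rate)
  } else Inf
  t_loss <- if (dropout$loss_rate > 0) rexp(1, dropout$loss_rate) else Inf
  t_end <- min(t_death, t_loss, dropout$admin_horizon)

  times <- numeric(0)
  values <- numeric(0)
  termination <- if (t_end == dropout$admin_horizon) {
    "administrative"
  } else if (t_death <= t_loss) "death" else "lost"

  t_now <- 0
  unsuitable <- FALSE
  repeat {
    y <- max(level(t_now) + .draw_errors(truth, 1L), 0.5)
    times <- c(times, t_now)
    values <- c(values, y)
    # surgery referral on this scan?
    ns <- length(values)
    rapid <- FALSE
    if (ns >= 2L) {
      dt <- times[ns] - times[ns - 1L]
      dy <- values[ns] - values[ns - 1L]
      # absolute observed increase of >= trigger mm within about a year
      rapid <- dt <= 1.25 && dy >= dropout$rapid_growth_trigger
    }
    if ((y >= dropout$surgery_threshold || rapid) && !unsuitable) {
      # referral: surgery unless the patient is deemed unsuitable, in
      # which case surveillance continues for good
      if (runif(1) <= dropout$referral_prob) {
        termination <- "surgery"
        break
      }
      unsuitable <- TRUE
    }
    # book the next appointment from the current observed value
    band <- findInterval(y, schedule$band_breaks) + 1L
    t_next <- t_now + schedule$intervals[band]
    repeat {
      t_prop <- t_next + rnorm(1, 0, schedule$jitter_sd)
      attended <- runif(1) <= schedule$attendance_prob
      if (t_prop < t_now + schedule$min_gap) t_prop <- t_now + schedule$min_gap
      if (t_prop > t_end) break
      if (attended) break
      t_next <- t_next + schedule$intervals[band] # skipped, not rescheduled
    }
    if (t_prop > t_end || !attended) break
    t_now <- t_prop
  }
  list(measurements = data.frame(time = times, value = values),
       termination = termination, b = b)
}

#' Simulate a synthetic screening cohort with known truth
#'
#' Aggregates [simulate_subject()] over a cohort, applying the configured
#' entry filter and optionally emitting left-censored records for a
#' sub-threshold screening population.  Each subject is generated in its own
#' RNG substream derived from `config$seed`, so a given `(seed, subject
#' index)` always yields the same series regardless of `n_subjects`.
#'
#' @param config a [generator_config()] object.
#' @return a list of class `aaa_sim` with elements `cohort` (an
#'   [aaa_cohort]), `truth` (the generating [truth_params()]), `b` (matrix
#'   of the generating random effects of followed subjects) and counts of
#'   rejected / censored screens.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "aaa_genconfig"))
  truth <- config$truth
  n <- config$n_subjects
  covs <- NULL
  if (!is.null(config$covariate_gen)) {
    set.seed(.substream(config$seed, 0L))
    covs <- as.data.frame(config$covariate_gen(n))
  }

  meas <- vector("list", n)
  term <- character(n)
  bmat <- matrix(NA_real_, n, length(truth$beta))
  n_rejected_low <- 0L
  n_rejected_high <- 0L
  cens_rows <- list()

  for (i in seq_len(n)) {
    set.seed(.substream(config$seed, i))
    zi <- if (is.null(covs)) NULL else {
      setNames(as.numeric(covs[i, , drop = FALSE]), names(covs))
    }
    for (try in seq_len(1000L)) {
      sub <- simulate_subject(truth, config$schedule, config$dropout,
                              covariates = zi,
                              subject_id = paste0("s", i))
      y0 <- sub$measurements$value[1]
      if (config$entry_filter == "none") break
      if (y0 >= 30 && y0 < 55) break
      if (config$entry_filter == "censor" && y0 < 30) {
        # a screen below the aneurysm definition: record only the bound
        cens_rows[[length(cens_rows) + 1L]] <-
          data.frame(subject_id = sprintf("s%d_c%d", i, try),
                     time = 0, value = NA_real_, censor_bound = 30,
                     stringsAsFactors = FALSE)
        next
      }
      if (y0 < 30) n_rejected_low <- n_rejected_low + 1L
      else n_rejected_high <- n_rejected_high + 1L
      if (try == 1000L) {
        stop(sprintf(paste0("entry filter rejected 1000 consecutive draws ",
                            "for subject %d (%d low, %d high); check the ",
                            "generating truth"),
                     i, n_rejected_low, n_rejected_high), call. = FALSE)
      }
    }
    meas[[i]] <- cbind(subject_id = paste0("s", i), sub$measurements,
                       censor_bound = NA_real_)
    term[i] <- sub$termination
    bmat[i, ] <- sub$b
  }

  if (config$censor_population_n > 0L) {
    set.seed(.substream(config$seed, n + 1L))
    npool <- config$censor_population_n
    bpool <- draw_subject_effects(truth, npool)
    y0 <- truth$beta[1] + bpool[, 1] + .draw_errors(truth, npool)
    k <- which(y0 < 30)
    if (length(k)) {
      cens_rows[[length(cens_rows) + 1L]] <-
        data.frame(subject_id = sprintf("pop%d", k),
                   time = 0, value = NA_real_, censor_bound = 30,
                   stringsAsFactors = FALSE)
    }
  }

  m <- do.call(rbind, c(meas, cens_rows))
  ids <- paste0("s", seq_len(n))
  subj <- data.frame(subject_id = ids, termination = term,
                     stringsAsFactors = FALSE)
  if (!is.null(covs)) subj <- cbind(subj, covs)
  if (length(cens_rows)) {
    extra <- unique(unlist(lapply(cens_rows, `[[`, "subject_id")))
    pad <- data.frame(subject_id = extra, termination = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(covs)) for (cn in names(covs)) pad[[cn]] <- NA_real_
    subj <- rbind(subj, pad)
  }
  cohort <- aaa_cohort(m, subj)
  structure(list(cohort = cohort, truth = truth, b = bmat,
                 n_rejected = c(low = n_rejected_low,
                                high = n_rejected_high),
                 n_censored_records = length(unlist(
                   lapply(cens_rows, `[[`, "subject_id")))),
            class = "aaa_sim")
}

# Derive a per-subject substream seed from the global seed; kept within
# 32-bit integer range.
.substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647)
}
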