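#' Validate predicted exceedance proportions by multiple imputation
#'
#' Checks the calibration of the model's individual-level predictions the
#' way a screening programme would: form a prediction set from each
#' individual's first `k` scans, treat each as a new patient (cut
#' posterior), and compute the predicted probability that a measurement at
#' years 1..5 after screening would be at or above `alpha`.  The mean of
#' these probabilities over individuals is the predicted proportion.
#'
#' Observed proportions cannot be used directly as the comparator, because
#' individuals with large measurements leave the cohort (surgery), making
#' late observed samples unrepresentative.  Instead, multiply imputed
#' complete data sets are formed: for each individual and year `x`, the
#' observed scan nearest `x` is used when one exists within `window`
#' years (ties to the earlier scan); otherwise the measurement is imputed
#' from the individual's posterior predictive at `x`, conditioning on
#' *all* their data.  The proportion at or above `alpha` is averaged over
#' imputations.
#'
#' @param population an `aaa_fit` (fitted on an analysis set).
#' @param prediction_cohort the [aaa_cohort] to validate on; subjects with
#'   fewer than `k` scans contribute all the scans they have.
#' @param k_scans numbers of initial scans used for prediction.
#' @param years prediction years after screening.
#' @param window half-width (years) around each year within which an
#'   observed scan may stand in for it.
#' @param alpha threshold (mm).
#' @param n_imputations number of imputed data sets.
#' @param seed seed for the cut sampling and imputation draws.
#' @return a data frame of class `aaa_validation`: one row per `(k, year)`
#'   with `predicted` and `comparator` proportions and the fraction of
#'   comparator cells that had to be imputed at that year.
#' @export
validate_predictions <- function(population, prediction_cohort,
                                 k_scans = 1:3, years = 1:5,
                                 window = 0.5, alpha = 55,
                                 n_imputations = 100, seed = 1) {
  stopifnot(inherits(population, "aaa_fit"),
            inherits(prediction_cohort, "aaa_cohort"),
            n_imputations >= 2)
  m <- prediction_cohort$measurements
  obs <- m[!is.na(m$value), , drop = FALSE]
  ids <- unique(obs$subject_id)
  n <- length(ids)
  if (n == 0L) stop("empty prediction set", call. = FALSE)
  bysub <- split(obs[c("time", "value")], factor(obs$subject_id, ids))
  covs <- NULL
  if (length(population$model$covariates)) {
    covs <- prediction_cohort$subjects
  }
  getz <- function(id) {
    if (is.null(covs)) return(NULL)
    unlist(covs[match(id, covs$subject_id),
                population$model$covariates, drop = TRUE])
  }
  K <- nrow(population$theta)
  imp_idx <- NULL # draw indices used for the imputations

  # predicted proportions from the first k scans
  pred <- matrix(NA_real_, length(k_scans), length(years),
                 dimnames = list(paste0("k", k_scans), years))
  for (ki in seq_along(k_scans)) {
    k <- k_scans[ki]
    psum <- numeric(length(years))
    for (i in seq_len(n)) {
      di <- bysub[[i]]
      use <- seq_len(min(k, nrow(di)))
      ind <- individual_posterior(population, times = di$time[use],
                                  values = di$value[use],
                                  covariates = getz(ids[i]),
                                  seed = .substream(seed, i * 10L + ki))
      psum <- psum + exceedance_prob(ind, t = 0, s = years, alpha = alpha)
    }
    pred[ki, ] <- psum / n
  }

  # multiply imputed comparator, conditioning on all data
  set.seed(.substream(seed, 999000L))
  imp_idx <- sample.int(K, n_imputations, replace = n_imputations > K)
  cell_obs <- matrix(NA_real_, n, length(years))
  imput <- array(NA_real_, c(n, length(years), n_imputations))
  for (i in seq_len(n)) {
    di <- bysub[[i]]
    ind <- individual_posterior(population, times = di$time,
                                values = di$value,
                                covariates = getz(ids[i]),
                                seed = .substream(seed, 500000L + i))
    for (xi in seq_along(years)) {
      x <- years[xi]
      gap <- abs(di$time - x)
      j <- which(gap <= window)
      if (length(j)) {
        # nearest scan; ties broken toward the earlier scan
        j <- j[order(gap[j], di$time[j])][1L]
        cell_obs[i, xi] <- di$value[j]
      } else {
        mu <- ind$coef[imp_idx, "A"] + ind$coef[imp_idx, "B"] * x +
          ind$coef[imp_idx, "C"] * x * x
        err <- if (population$model$error_family == "student_t") {
          ind$sigma_w[imp_idx] * rt(n_imputations,
                                    df = ind$nu[imp_idx])
        } else {
          rnorm(n_imputations, 0, ind$sigma_w[imp_idx])
        }
        imput[i, xi, ] <- mu + err
      }
    }
  }
  comp <- numeric(length(years))
  frac_imp <- numeric(length(years))
  for (xi in seq_along(years)) {
    observed <- !is.na(cell_obs[, xi])
    frac_imp[xi] <- mean(!observed)
    props <- vapply(seq_len(n_imputations), function(mm) {
      vals <- cell_obs[, xi]
      vals[!observed] <- imput[!observed, xi, mm]
      mean(vals >= alpha)
    }, 0)
    comp[xi] <- mean(props)
  }

  out <- expand.grid(year = years, k = k_scans)
  out$predicted <- as.vector(t(pred))
  out$comparator <- rep(comp, length(k_scans))
  out$frac_imputed <- rep(frac_imp, length(k_scans))
  class(out) <- c("aaa_validation", "data.frame")
  out
}

#' @export
print.aaa_validation <- function(x, ...) {
  cat("predicted vs multiply-imputed proportions >= threshold\n")
  df <- as.data.frame(x)
  df$predicted <- sprintf("%.1f%%", 100 * df$predicted)
  df$comparator <- sprintf("%.1f%%", 100 * df$comparator)
  df$frac_imputed <- sprintf("%.0f%%", 100 * df$frac_imputed)
  print(df, row.names = FALSE)
  invisible(x)
}
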