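#' Longitudinal cohort of diameter measurement series
#'
#' An `aaa_cohort` holds repeated diameter measurements for a set of
#' subjects, together with optional baseline covariates and the way each
#' series terminated.  Measurements are `(subject_id, time, value)` triples;
#' a record may instead be left-censored, meaning only that the diameter lay
#' below a known bound (e.g. a screen reported as "under 30 mm").  Times are
#' years since each subject's time origin (screening by default) and values
#' are millimetres.
#'
#' @param measurements data frame with columns `subject_id`, `time`,
#'   `value`, and optionally `censor_bound`.  Exactly one of `value` /
#'   `censor_bound` must be non-`NA` on every row; `time` must be
#'   non-negative and strictly increasing within subject.
#' @param subjects optional data frame with one row per subject: column
#'   `subject_id`, optional `termination` (one of `"administrative"`,
#'   `"surgery"`, `"death"`, `"lost"` or `NA`), and any number of numeric
#'   baseline covariate columns.  Defaults to the distinct subject ids with
#'   no covariates.
#' @param time_origin_label free-text label for the time origin.
#'
#' @return an object of class `aaa_cohort`: a list with elements
#'   `measurements`, `subjects`, `covariate_names` and `time_origin_label`.
#' @export
aaa_cohort <- function(measurements, subjects = NULL,
                       time_origin_label = "screening") {
  stopifnot(is.data.frame(measurements))
  req <- c("subject_id", "time", "value")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns subject_id, time, value",
         call. = FALSE)
  }
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  m$subject_id <- as.character(m$subject_id)
  m$time <- as.numeric(m$time)
  m$value <- as.numeric(m$value)
  if (is.null(m$censor_bound)) m$censor_bound <- NA_real_
  m$censor_bound <- as.numeric(m$censor_bound)
  m <- m[c("subject_id", "time", "value", "censor_bound")]

  if (anyNA(m$time) || any(m$time < 0)) {
    stop("measurement times must be non-negative numbers", call. = FALSE)
  }
  one_of <- xor(!is.na(m$value), !is.na(m$censor_bound))
  if (!all(one_of)) {
    stop("each measurement must have exactly one of value / censor_bound",
         call. = FALSE)
  }
  if (any(!is.na(m$value) & m$value <= 0)) {
    stop("diameter values must be positive", call. = FALSE)
  }
  if (all(is.na(m$value))) {
    stop("cohort must contain at least one non-censored measurement",
         call. = FALSE)
  }
  ord <- order(m$subject_id, m$time)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  dup <- duplicated(m[c("subject_id", "time")])
  if (any(dup)) {
    stop("duplicate (subject_id, time) pairs: ",
         paste(utils::head(m$subject_id[dup], 3L), collapse = ", "),
         call. = FALSE)
  }

  ids <- unique(m$subject_id)
  if (is.null(subjects)) {
    subjects <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  }
  s <- as.data.frame(subjects, stringsAsFactors = FALSE)
  s$subject_id <- as.character(s$subject_id)
  if (anyDuplicated(s$subject_id)) {
    stop("subject_ids must be unique", call. = FALSE)
  }
  if (!setequal(s$subject_id, ids)) {
    stop("subjects table must list exactly the subjects present in ",
         "measurements", call. = FALSE)
  }
  s <- s[match(ids, s$subject_id), , drop = FALSE]
  rownames(s) <- NULL
  if (is.null(s$termination)) s$termination <- NA_character_
  ok_term <- is.na(s$termination) |
    s$termination %in% c("administrative", "surgery", "death", "lost")
  if (!all(ok_term)) {
    stop("termination must be administrative/surgery/death/lost or NA",
         call. = FALSE)
  }
  covariate_names <- setdiff(names(s), c("subject_id", "termination"))
  for (cn in covariate_names) s[[cn]] <- as.numeric(s[[cn]])
  s <- s[c("subject_id", "termination", covariate_names)]

  structure(
    list(measurements = m, subjects = s,
         covariate_names = covariate_names,
         time_origin_label = as.character(time_origin_label)),
    class = "aaa_cohort"
  )
}

#' Read a cohort from delimited text
#'
#' Reads a comma-separated file (header row required, UTF-8) with columns
#' `subject_id`, `time`, `value`, and optionally `censor_bound`,
#' `termination` and numeric covariate columns.  Covariates and termination
#' are baseline (subject-level) quantities and must be constant within
#' subject.  Rows are grouped by subject and sorted by time; duplicate
#' `(subject, time)` pairs, negative times and non-numeric values are
#' rejected.
#'
#' @param path file path.
#' @param time_origin_label label recorded on the returned cohort.
#' @return an [aaa_cohort] object.
#' @seealso [write_cohort()] for the inverse operation; the pair round-trips
#'   losslessly.
#' @export
read_cohort <- function(path, time_origin_label = "screening") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  req <- c("subject_id", "time", "value")
  if (!all(req %in% names(raw))) {
    stop("file must have columns subject_id, time, value", call. = FALSE)
  }
  num <- function(x, what) {
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out) & !is.na(x))) {
      stop("non-numeric ", what, " in ", path, call. = FALSE)
    }
    out
  }
  m <- data.frame(subject_id = raw$subject_id,
                  time = num(raw$time, "time"),
                  value = num(raw$value, "value"),
                  stringsAsFactors = FALSE)
  if ("censor_bound" %in% names(raw)) {
    m$censor_bound <- num(raw$censor_bound, "censor_bound")
  }
  cov_cols <- setdiff(names(raw), c("subject_id", "time", "value",
                                    "censor_bound", "termination"))
  first <- !duplicated(raw$subject_id)
  s <- data.frame(subject_id = raw$subject_id[first],
                  stringsAsFactors = FALSE)
  if ("termination" %in% names(raw)) {
    term <- raw$termination
    term[!nzchar(term)] <- NA_character_
    s$termination <- term[first]
    if (!all(tapply(term, raw$subject_id,
                    function(x) length(unique(x)) == 1L))) {
      stop("termination must be constant within subject", call. = FALSE)
    }
  }
  for (cn in cov_cols) {
    v <- num(raw[[cn]], cn)
    if (!all(tapply(v, raw$subject_id,
                    function(x) length(unique(x)) == 1L))) {
      stop("covariate '", cn, "' must be constant within subject",
           call. = FALSE)
    }
    s[[cn]] <- v[first]
  }
  aaa_cohort(m, s, time_origin_label = time_origin_label)
}

#' Write a cohort to delimited text
#'
#' Writes the comma-separated representation read by [read_cohort()].
#' Numeric fields are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces every parsed field exactly.
#' Covariate columns are emitted only when the cohort has covariates; a
#' `censor_bound` column only when censored records are present.
#'
#' @param cohort an [aaa_cohort].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  m <- cohort$measurements
  s <- cohort$subjects
  idx <- match(m$subject_id, s$subject_id)
  fmt <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
  }
  df <- data.frame(subject_id = m$subject_id,
                   time = fmt(m$time), value = fmt(m$value),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (any(!is.na(m$censor_bound))) df$censor_bound <- fmt(m$censor_bound)
  if (any(!is.na(s$termination))) {
    term <- s$termination[idx]
    term[is.na(term)] <- ""
    df$termination <- term
  }
  for (cn in cohort$covariate_names) df[[cn]] <- fmt(s[[cn]][idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Descriptive summary of a cohort
#'
#' Computes the descriptive quantities used to characterise a screening
#' cohort: number of subjects, total scan count, mean scans per person,
#' mean follow-up (years from each subject's first to last scan), counts of
#' baseline (first observed) diameters in 5 mm bins, termination-mode
#' proportions, and the number of left-censored records.  Censored-only
#' subjects (e.g. a sub-threshold screening population) are tallied
#' separately and excluded from the scan/follow-up statistics.
#'
#' @param cohort an [aaa_cohort].
#' @return a list of class `aaa_cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  m <- cohort$measurements
  obs <- m[!is.na(m$value), , drop = FALSE]
  ids_obs <- unique(obs$subject_id)
  n_cens_only <- length(unique(m$subject_id)) - length(ids_obs)
  scans <- tabulate(factor(obs$subject_id, levels = ids_obs))
  span <- tapply(obs$time, factor(obs$subject_id, levels = ids_obs),
                 function(t) max(t) - min(t))
  baseline <- obs$value[!duplicated(obs$subject_id)]
  breaks <- seq(floor(min(baseline) / 5) * 5,
                ceiling(max(baseline + 1e-9) / 5) * 5, by = 5)
  hist_counts <- table(cut(baseline, breaks, right = FALSE))
  term <- cohort$subjects$termination
  term <- term[cohort$subjects$subject_id %in% ids_obs]
  structure(
    list(n_subjects = length(ids_obs),
         n_measurements = nrow(obs),
         n_censored_records = sum(!is.na(m$censor_bound)),
         n_censored_only_subjects = n_cens_only,
         mean_scans = mean(scans),
         mean_followup = mean(as.numeric(span)),
         baseline_hist = hist_counts,
         termination = if (any(!is.na(term))) {
           prop.table(table(term, useNA = "no"))
         } else NULL),
    class = "aaa_cohort_summary"
  )
}

#' @export
print.aaa_cohort <- function(x, ...) {
  m <- x$measurements
  cat("aaa_cohort:", nrow(x$subjects), "subjects,",
      sum(!is.na(m$value)), "measurements",
      if (any(!is.na(m$censor_bound))) {
        paste0("(+", sum(!is.na(m$censor_bound)), " censored records)")
      } else "",
      "\n")
  if (length(x$covariate_names)) {
    cat("covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  }
  cat("time origin:", x$time_origin_label, "\n")
  invisible(x)
}

#' @export
print.aaa_cohort_summary <- function(x, ...) {
  cat("subjects:", x$n_subjects,
      " measurements:", x$n_measurements, "\n")
  cat(sprintf("mean scans/person: %.2f   mean follow-up: %.2f years\n",
              x$mean_scans, x$mean_followup))
  if (x$n_censored_records > 0) {
    cat("censored records:", x$n_censored_records,
        " censored-only subjects:", x$n_censored_only_subjects, "\n")
  }
  cat("baseline diameter bins:\n")
  print(x$baseline_hist)
  if (!is.null(x$termination)) {
    cat("termination proportions:\n")
    print(round(x$termination, 3))
  }
  invisible(x)
}

# Split a cohort's plain (non-censored) measurements into per-fit vectors.
# Returns NULL-covariate design when the model requests none.
.cohort_arrays <- function(cohort) {
  m <- cohort$measurements
  obs <- m[!is.na(m$value), , drop = FALSE]
  ids <- unique(obs$subject_id)
  id <- match(obs$subject_id, ids)
  list(y = obs$value, t = obs$time, id = id, ids = ids,
       n = length(ids), N = nrow(obs))
}

# Subject-level covariate matrix (n x p) in the order of `ids`.
.cohort_covariates <- function(cohort, ids, covariate_names) {
  if (length(covariate_names) == 0L) return(NULL)
  missing <- setdiff(covariate_names, cohort$covariate_names)
  if (length(missing)) {
    stop("cohort lacks covariates required by the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- cohort$subjects
  Z <- as.matrix(s[match(ids, s$subject_id), covariate_names, drop = FALSE])
  if (anyNA(Z)) stop("missing covariate values", call. = FALSE)
  storage.mode(Z) <- "double"
  Z
}
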