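#' Construct a cohort of scored patients
#'
#' A cohort is the central input of the pipeline: one row per patient with an
#' integer early-warning score and a binary vital status (deceased = 1 is the
#' modelled event throughout the package).
#'
#' @param score integer vector of MEWS values, all >= 0.
#' @param outcome binary vector, 1 = deceased, 0 = alive. The string aliases
#'   `"deceased"` and `"alive"` (case-insensitive) are also accepted.
#' @param patient_id optional character vector of identifiers; sequential ids
#'   `P0001, P0002, ...` are generated when omitted.
#' @return A data frame of class `mews_cohort` with columns
#'   `patient_id`, `score`, `outcome`.
#' @examples
#' coh <- mews_cohort(score = c(0, 1, 1), outcome = c(0, 0, 1))
#' summary(coh)
#' @export
mews_cohort <- function(score, outcome, patient_id = NULL) {
  score <- as_score(score)
  outcome <- as_outcome(outcome)
  if (length(score) != length(outcome)) {
    stop("`score` and `outcome` must have equal length", call. = FALSE)
  }
  if (is.null(patient_id)) {
    patient_id <- sprintf("P%04d", seq_along(score))
  }
  patient_id <- as.character(patient_id)
  if (length(patient_id) != length(score)) {
    stop("`patient_id` must match `score` in length", call. = FALSE)
  }
  structure(
    data.frame(patient_id = patient_id, score = score, outcome = outcome,
               stringsAsFactors = FALSE),
    class = c("mews_cohort", "data.frame")
  )
}

as_score <- function(x, what = "score") {
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) | xn != round(xn) | xn < 0)
  if (length(bad)) {
    stop(sprintf("non-integer or negative %s at row %d: '%s'",
                 what, bad[1], as.character(x[bad[1]])), call. = FALSE)
  }
  as.integer(xn)
}

as_outcome <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- tolower(trimws(as.character(x)))
    map <- c(alive = 0, deceased = 1, "0" = 0, "1" = 1)
    out <- unname(map[x])
  } else {
    out <- as.numeric(x)
    out[!(out %in% c(0, 1))] <- NA_real_
  }
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("outcome outside {0, 1, alive, deceased} at row %d: '%s'",
                 bad[1], as.character(x[bad[1]])), call. = FALSE)
  }
  as.integer(out)
}

#' @export
summary.mews_cohort <- function(object, ...) {
  n <- nrow(object)
  nd <- sum(object$outcome == 1L)
  structure(list(n = n, n_deceased = nd, n_alive = n - nd,
                 score_range = if (n) range(object$score) else c(NA, NA)),
            class = "summary.mews_cohort")
}

#' @export
print.summary.mews_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d deceased, %d alive)\n",
              x$n, x$n_deceased, x$n_alive))
  if (x$n) cat(sprintf("Score range: %d-%d\n", x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' @export
print.mews_cohort <- function(x, ...) {
  print(summary(x))
  NextMethod()
}

#' Read a per-patient cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `patient_id`, `score`, `outcome`. Outcomes may be coded 0/1 or
#' alive/deceased.
#'
#' @param path path to the CSV file.
#' @return A [mews_cohort].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("patient_id", "score", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  mews_cohort(score = df$score, outcome = df$outcome, patient_id = df$patient_id)
}

#' Write a cohort to CSV
#'
#' Outcomes are written as integers (deceased = 1). Output is deterministic:
#' the same cohort always produces byte-identical files.
#'
#' @param cohort a [mews_cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "mews_cohort"))
  utils::write.csv(as.data.frame(cohort)[c("patient_id", "score", "outcome")],
                   path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Compress a cohort to per-score outcome counts
#'
#' @param cohort a [mews_cohort].
#' @return A data frame of class `score_counts` with one row per integer score
#'   from 0 to the maximum observed, columns `score`, `deaths`, `survivors`.
#' @export
score_counts <- function(cohort) {
  stopifnot(inherits(cohort, "mews_cohort"))
  if (!nrow(cohort)) stop("empty cohort has no counts", call. = FALSE)
  s_max <- max(cohort$score)
  s <- 0:s_max
  deaths <- vapply(s, function(k) sum(cohort$score == k & cohort$outcome == 1L), 0L)
  survivors <- vapply(s, function(k) sum(cohort$score == k & cohort$outcome == 0L), 0L)
  new_score_counts(s, deaths, survivors)
}

new_score_counts <- function(score, deaths, survivors) {
  stopifnot(all(deaths >= 0), all(survivors >= 0),
            identical(as.integer(score), seq(0L, length(score) - 1L)))
  structure(
    data.frame(score = as.integer(score), deaths = as.integer(deaths),
               survivors = as.integer(survivors)),
    class = c("score_counts", "data.frame")
  )
}

#' Expand per-score counts to a full per-patient cohort
#'
#' The inverse of [score_counts()]. Record order is fixed (ascending score,
#' deceased before alive) and patient ids are sequential, so expansion is
#' fully deterministic and CSV round-trips are byte-identical.
#'
#' @param counts a `score_counts` data frame.
#' @return A [mews_cohort].
#' @export
expand_to_cohort <- function(counts) {
  stopifnot(inherits(counts, "score_counts"))
  score <- integer(0)
  outcome <- integer(0)
  for (i in seq_len(nrow(counts))) {
    score <- c(score, rep(counts$score[i], counts$deaths[i] + counts$survivors[i]))
    outcome <- c(outcome, rep(1L, counts$deaths[i]), rep(0L, counts$survivors[i]))
  }
  mews_cohort(score = score, outcome = outcome)
}

#' Cumulate per-score counts into a threshold cross-classification table
#'
#' For each threshold T (descending from the maximum score to 0), counts the
#' 2x2 cells of the rule "predict deceased iff score >= T", with deceased as
#' the positive class: `tp[T]` is the number of deaths at scores >= T, `fp[T]`
#' the number of survivors at scores >= T, and `fn`/`tn` follow from the fixed
#' class margins.
#'
#' @param counts a `score_counts` data frame.
#' @return A data frame of class `threshold_table` with columns
#'   `threshold`, `tp`, `tn`, `fp`, `fn`, thresholds descending.
#' @export
cumulate_counts <- function(counts) {
  stopifnot(inherits(counts, "score_counts"))
  d_total <- sum(counts$deaths)
  s_total <- sum(counts$survivors)
  thr <- rev(counts$score)              # descending
  tp <- cumsum(rev(counts$deaths))
  fp <- cumsum(rev(counts$survivors))
  new_threshold_table(thr, tp = tp, fp = fp,
                      fn = d_total - tp, tn = s_total - fp)
}

new_threshold_table <- function(threshold, tp, tn, fp, fn) {
  df <- data.frame(threshold = as.integer(threshold), tp = as.integer(tp),
                   tn = as.integer(tn), fp = as.integer(fp), fn = as.integer(fn))
  df <- df[order(-df$threshold), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("threshold_table", "data.frame"))
}

validate_threshold_table <- function(tab) {
  stopifnot(inherits(tab, "threshold_table"))
  if (!nrow(tab)) stop("empty threshold table", call. = FALSE)
  d <- unique(tab$tp + tab$fn)
  s <- unique(tab$tn + tab$fp)
  if (length(d) != 1L || length(s) != 1L) {
    stop("inconsistent margins: tp+fn and tn+fp must be constant across thresholds",
         call. = FALSE)
  }
  # rows are sorted descending in threshold; cumulative counts grow downward
  if (is.unsorted(tab$tp) || is.unsorted(tab$fp)) {
    stop("non-monotone cumulative counts: tp and fp must be non-increasing in threshold",
         call. = FALSE)
  }
  if (any(diff(tab$threshold) != -1L)) {
    stop("thresholds must be consecutive integers", call. = FALSE)
  }
  invisible(tab)
}

#' Recover per-score outcome counts from a cumulative threshold table
#'
#' Exact inversion of [cumulate_counts()] by differencing: the number of
#' deaths at score s is `tp[s] - tp[s+1]` (with tp above the maximum
#' threshold taken as 0) and likewise for survivors from the false-positive
#' column. Forward re-cumulation of the result reproduces the input exactly,
#' which is how a per-patient cohort is reconstructed from a published
#' cross-classification table.
#'
#' @param tab a `threshold_table` (thresholds must be consecutive integers
#'   down to 0, cumulative counts monotone, margins constant).
#' @return A `score_counts` data frame.
#' @export
invert_cumulative_table <- function(tab) {
  validate_threshold_table(tab)
  if (min(tab$threshold) != 0L) {
    stop("threshold table must extend down to threshold 0", call. = FALSE)
  }
  asc <- tab[order(tab$threshold), , drop = FALSE]
  deaths <- asc$tp - c(asc$tp[-1], 0L)
  survivors <- asc$fp - c(asc$fp[-1], 0L)
  new_score_counts(asc$threshold, deaths, survivors)
}

#' Read / write a threshold cross-classification table
#'
#' CSV columns: `threshold,tp,tn,fp,fn`.
#'
#' @param path file path.
#' @return `read_threshold_table_csv()` returns a `threshold_table`.
#' @export
read_threshold_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("threshold", "tp", "tn", "fp", "fn")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  tab <- new_threshold_table(df$threshold, df$tp, df$tn, df$fp, df$fn)
  validate_threshold_table(tab)
}

#' @rdname read_threshold_table_csv
#' @param tab a `threshold_table`.
#' @export
write_threshold_table_csv <- function(tab, path) {
  stopifnot(inherits(tab, "threshold_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' The packaged surgical-ICU escalation reference cohort
#'
#' The package ships the cumulative threshold cross-classification table of a
#' published 263-patient cohort of consecutive unplanned surgical-ICU
#' escalations (77 deaths, 186 survivors, MEWS 0-8). Because the table's
#' cumulative true-positive and false-positive columns are exact counts, the
#' per-patient (score, outcome) data are fully recoverable by differencing;
#' `sicu_cohort()` performs that reconstruction.
#'
#' @return `sicu_threshold_table()` returns the packaged `threshold_table`;
#'   `sicu_cohort()` the reconstructed 263-patient [mews_cohort].
#' @export
sicu_threshold_table <- function() {
  read_threshold_table_csv(
    system.file("extdata", "sicu_escalation_table.csv", package = "mewseval",
                mustWork = TRUE))
}

#' @rdname sicu_threshold_table
#' @export
sicu_cohort <- function() {
  expand_to_cohort(invert_cumulative_table(sicu_threshold_table()))
}
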