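#' Oriented 2x2 confusion matrix
#'
#' Cells follow the classical diagnostic layout: `a` = true positives, `b` =
#' false positives, `c` = false negatives, `d` = true negatives, with row
#' margins `r1 = a + b` (predicted positive), `r2 = c + d`, column margins
#' `c1 = a + c` (actual positive), `c2 = b + d`, and total `t`. The positive
#' class is explicit metadata: internal computations in this package use the
#' deceased-positive orientation, while the published confusion-matrix view
#' labels survival as the positive class; [flip_orientation()] maps between
#' the two.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param positive label of the positive class (e.g. `"deceased"` or
#'   `"alive"`).
#' @param negative label of the negative class.
#' @return A list of class `confusion_matrix` with cells, margins, total and
#'   orientation labels.
#' @export
confusion_matrix <- function(a, b, c, d, positive = "deceased",
                             negative = if (positive == "deceased") "alive" else "deceased") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  structure(list(
    a = a, b = b, c = c, d = d,
    r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d, t = a + b + c + d,
    positive = positive, negative = negative
  ), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param m a `confusion_matrix`.
#' @export
flip_orientation <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  confusion_matrix(m$d, m$c, m$b, m$a, positive = m$negative, negative = m$positive)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive class: %s)\n", x$positive))
  tab <- matrix(c(x$a, x$b, x$r1, x$c, x$d, x$r2, x$c1, x$c2, x$t),
                nrow = 3, byrow = TRUE,
                dimnames = list(
                  c(sprintf("Predicted %s", x$positive),
                    sprintf("Predicted %s", x$negative), "Totals"),
                  c(sprintf("Actual %s", x$positive),
                    sprintf("Actual %s", x$negative), "Totals")))
  print(tab)
  invisible(x)
}

#' Classify a cohort at a score threshold
#'
#' Applies the rule "predict deceased iff score >= threshold" and tabulates
#' it against the true outcome in deceased-positive orientation.
#'
#' @param cohort a [mews_cohort].
#' @param threshold integer score threshold.
#' @return A deceased-positive [confusion_matrix].
#' @export
classification_at_threshold <- function(cohort, threshold) {
  stopifnot(inherits(cohort, "mews_cohort"), nrow(cohort) > 0)
  pred <- cohort$score >= threshold
  dead <- cohort$outcome == 1L
  confusion_matrix(
    a = sum(pred & dead), b = sum(pred & !dead),
    c = sum(!pred & dead), d = sum(!pred & !dead),
    positive = "deceased")
}

#' Scan every score threshold
#'
#' One row per threshold from the maximum observed score down to 0, with the
#' sensitivity, 1 - specificity and their difference (the Youden-type
#' quantity driving cut-point selection) of the rule "predict deceased iff
#' score >= threshold", in percent, plus the four cell counts
#' (deceased-positive orientation). If a fitted model is supplied, the fitted
#' mortality probability at each threshold score is prepended, mirroring the
#' published per-score table layout.
#'
#' @param cohort a [mews_cohort].
#' @param fit optional converged `mews_logit` for the probability column.
#' @return A data frame of class `threshold_scan` with columns `threshold`,
#'   optionally `probability_pct`, `sensitivity_pct`, `one_minus_specificity_pct`,
#'   `youden_diff_pct`, `tp`, `tn`, `fp`, `fn`.
#' @export
threshold_scan <- function(cohort, fit = NULL) {
  stopifnot(inherits(cohort, "mews_cohort"), nrow(cohort) > 0)
  thr <- seq(max(cohort$score), 0L)
  rows <- lapply(thr, function(T) {
    m <- classification_at_threshold(cohort, T)
    sens <- 100 * m$a / m$c1
    one_minus_spec <- 100 * m$b / m$c2
    data.frame(threshold = T,
               sensitivity_pct = sens,
               one_minus_specificity_pct = one_minus_spec,
               youden_diff_pct = sens - one_minus_spec,
               tp = m$a, tn = m$d, fp = m$b, fn = m$c)
  })
  scan <- do.call(rbind, rows)
  if (!is.null(fit)) {
    scan <- cbind(scan[1], probability_pct = 100 * predicted_probability(fit, scan$threshold),
                  scan[-1])
  }
  structure(scan, class = c("threshold_scan", "data.frame"))
}

#' Select the optimal cut-point from a threshold scan
#'
#' Returns the threshold maximizing sensitivity - (1 - specificity); ties are
#' broken toward the higher threshold (the more specific rule).
#'
#' @param scan a `threshold_scan`.
#' @return List with `threshold` and `youden_diff_pct` at the maximum.
#' @export
select_cutpoint <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"), nrow(scan) > 0)
  best <- max(scan$youden_diff_pct)
  at <- scan$threshold[scan$youden_diff_pct == best]
  list(threshold = max(at), youden_diff_pct = best)
}

#' Classify by fitted probability
#'
#' Applies the rule "predict deceased iff fitted mortality probability >
#' p_cut" and tabulates it against the true outcome. The matrix is emitted in
#' the survival-positive orientation of the published confusion-matrix table
#' (alive is labelled the positive class there); flip with
#' [flip_orientation()] for the conventional deceased-positive view.
#'
#' @param fit a converged `mews_logit` fitted on `cohort`.
#' @param cohort a [mews_cohort].
#' @param p_cut probability cut (default 0.5).
#' @return An alive-positive [confusion_matrix].
#' @export
classification_at_probability <- function(fit, cohort, p_cut = 0.5) {
  stopifnot(inherits(fit, "mews_logit"), inherits(cohort, "mews_cohort"))
  p <- predicted_probability(fit, cohort$score)
  pred_dead <- p > p_cut
  dead <- cohort$outcome == 1L
  confusion_matrix(
    a = sum(!pred_dead & !dead),  # predicted alive, actually alive
    b = sum(!pred_dead & dead),
    c = sum(pred_dead & !dead),
    d = sum(pred_dead & dead),
    positive = "alive")
}

#' Dichotomized cut-point model
#'
#' Splits the cohort at a score cut-point into exposed (score >= cut) and
#' unexposed groups and summarizes the association with death: the 2x2 table
#' (deceased-positive), cross-product odds ratio and relative risk with
#' log-delta intervals, the whole-model likelihood-ratio chi-square of the
#' logistic fit on the binary indicator, and the misclassification rate of
#' the rule "predict death iff score >= cut" with a Wilson interval.
#'
#' @param cohort a [mews_cohort].
#' @param cutpoint integer score cut.
#' @param level confidence level (default 0.95).
#' @return A list of class `dichotomized_model`.
#' @export
dichotomized_model <- function(cohort, cutpoint, level = 0.95) {
  stopifnot(inherits(cohort, "mews_cohort"))
  if (!any(cohort$score >= cutpoint) || !any(cohort$score < cutpoint)) {
    stop("both exposure groups (score >= cut and score < cut) must be non-empty",
         call. = FALSE)
  }
  m <- classification_at_threshold(cohort, cutpoint)
  or <- ratio_ci(m, "odds_ratio", level)
  rr <- ratio_ci(m, "relative_risk", level)

  ind <- mews_cohort(score = as.integer(cohort$score >= cutpoint),
                     outcome = cohort$outcome)
  fit <- fit_logistic(ind)
  wt <- whole_model_test(fit)

  mis_k <- m$b + m$c
  mis <- proportion_ci(mis_k, m$t, level)

  structure(list(
    cutpoint = cutpoint, matrix = m,
    odds_ratio = or, relative_risk = rr,
    chi_square = wt$chi_square, p_value = wt$p_value,
    misclassification = mis
  ), class = "dichotomized_model")
}

#' @export
print.dichotomized_model <- function(x, ...) {
  cat(sprintf("Dichotomized at score >= %d\n", x$cutpoint))
  cat(sprintf("OR = %.1f (%.1f to %.1f); RR = %.1f (%.1f to %.1f)\n",
              x$odds_ratio$estimate, x$odds_ratio$lower, x$odds_ratio$upper,
              x$relative_risk$estimate, x$relative_risk$lower, x$relative_risk$upper))
  cat(sprintf("Whole-model chi-square = %.1f, p = %.4f\n", x$chi_square, x$p_value))
  cat(sprintf("Misclassification = %.2f (%.2f to %.2f)\n",
              x$misclassification$estimate, x$misclassification$lower,
              x$misclassification$upper))
  invisible(x)
}
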