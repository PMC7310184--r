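#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return List with `estimate` (k/n), `lower`, `upper`; the interval always
#'   lies in `[0, 1]` and contains the point estimate.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- n + z^2
  centre <- (k + z^2 / 2) / denom
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / denom
  # clamp to [0,1] and guarantee containment of k/n against rounding error
  list(estimate = p,
       lower = min(max(0, centre - half), p),
       upper = max(min(1, centre + half), p))
}

#' Log-scale delta-method interval for a 2x2 ratio measure
#'
#' Computes the point estimate and `exp(log est +/- z * SE_log)` interval for
#' the cross-product odds ratio, relative risk, or positive/negative
#' likelihood ratio of an oriented [confusion_matrix], with the standard
#' delta-method standard errors on the log scale. When a required cell is
#' zero the point estimate is non-finite; the interval is then computed from
#' Haldane-Anscombe 0.5-corrected cells and the result is flagged
#' `corrected = TRUE`.
#'
#' @param m a [confusion_matrix].
#' @param which one of `"odds_ratio"`, `"relative_risk"`, `"lr_positive"`,
#'   `"lr_negative"`, `"diagnostic_odds_ratio"`, `"error_odds_ratio"`.
#' @param level confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `corrected`.
#' @export
ratio_ci <- function(m, which = c("odds_ratio", "relative_risk", "lr_positive",
                                  "lr_negative", "diagnostic_odds_ratio",
                                  "error_odds_ratio"),
                     level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  which <- match.arg(which)
  z <- stats::qnorm(1 - (1 - level) / 2)

  est_fun <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    switch(which,
      odds_ratio = list(est = (a / b) / (c / d),
                        se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
      diagnostic_odds_ratio = list(est = (a * d) / (b * c),
                        se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
      error_odds_ratio = list(est = (a * b) / (c * d),
                        se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
      relative_risk = list(est = (a / r1) / (c / r2),
                        se = sqrt(1 / a - 1 / r1 + 1 / c - 1 / r2)),
      lr_positive = list(est = (a / c1) / (b / c2),
                        se = sqrt(1 / a - 1 / c1 + 1 / b - 1 / c2)),
      lr_negative = list(est = (c / c1) / (d / c2),
                        se = sqrt(1 / c - 1 / c1 + 1 / d - 1 / c2)))
  }

  raw <- est_fun(m$a, m$b, m$c, m$d)
  zero_cell <- any(c(m$a, m$b, m$c, m$d) == 0)
  if (zero_cell) {
    corr <- est_fun(m$a + 0.5, m$b + 0.5, m$c + 0.5, m$d + 0.5)
    list(estimate = raw$est,
         lower = exp(log(corr$est) - z * corr$se),
         upper = exp(log(corr$est) + z * corr$se),
         corrected = TRUE)
  } else {
    list(estimate = raw$est,
         lower = exp(log(raw$est) - z * raw$se),
         upper = exp(log(raw$est) + z * raw$se),
         corrected = FALSE)
  }
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement between predicted and actual class:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d) / t` and chance agreement
#' `p_e = (r1 c1 + r2 c2) / t^2`. The interval is the large-sample
#' asymptotic one, `kappa +/- z * sqrt(p_o (1 - p_o) / (t (1 - p_e)^2))`.
#'
#' @param m a [confusion_matrix] with total >= 2.
#' @param level confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`.
#' @export
cohen_kappa <- function(m, level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$t < 2) stop("kappa requires at least 2 observations", call. = FALSE)
  t <- m$t
  p_o <- (m$a + m$d) / t
  p_e <- (m$r1 * m$c1 + m$r2 * m$c2) / t^2
  if (p_e == 1) {
    return(list(estimate = NaN, lower = NaN, upper = NaN))
  }
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (t * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = kap, lower = kap - z * se, upper = kap + z * se)
}

metric_row <- function(metric, x, note = "") {
  data.frame(metric = metric, estimate = x$estimate, lower = x$lower,
             upper = x$upper, note = note, stringsAsFactors = FALSE)
}

invert_interval <- function(est, ci_lower, ci_upper) {
  # 1/x over an interval; a sign-crossing interval has an infinite bound
  if (ci_lower <= 0 && ci_upper >= 0) {
    list(estimate = 1 / abs(est), lower = 1 / max(abs(ci_lower), abs(ci_upper)),
         upper = Inf)
  } else {
    bounds <- sort(1 / abs(c(ci_lower, ci_upper)))
    list(estimate = 1 / abs(est), lower = bounds[1], upper = bounds[2])
  }
}

#' The complete diagnostic-accuracy metric ledger
#'
#' Computes every classical 2x2 test statistic from an oriented
#' [confusion_matrix], each with a point estimate and 95% confidence
#' interval: class prevalences, kappa, sensitivity, specificity, predictive
#' values, likelihood ratios, cross-product odds ratio, relative risk,
#' diagnostic and error odds ratios, difference in proportions, number
#' needed to treat, absolute and relative risk reduction, Youden J, number
#' needed to diagnose, accuracy, misclassification rate, and number needed
#' to misdiagnose. All formulas act on the cells a, b, c, d and margins r1,
#' r2, c1, c2, t of the supplied orientation.
#'
#' Interval methods (point estimates are the substantive output; interval
#' methods are the package's choices): Wilson for simple proportions,
#' log-scale delta method for ratio measures (Haldane-Anscombe 0.5
#' correction when a cell is zero, flagged in the note column), asymptotic
#' interval for kappa, Wald for the difference in proportions, delta method
#' for Youden J; NNT/NND/NNM intervals invert the bounds of the underlying
#' difference, with sign-crossing intervals reported as an infinite upper
#' bound. Metrics with a zero denominator are reported as non-finite with a
#' reason in `note`, never dropped.
#'
#' @param m a [confusion_matrix] with t >= 1 and both actual-class margins
#'   >= 1.
#' @param level confidence level (default 0.95).
#' @return A data frame of class `metric_report` with columns `metric`,
#'   `estimate`, `lower`, `upper`, `note`; the source matrix is attached as
#'   attribute `matrix`.
#' @examples
#' m <- confusion_matrix(183, 73, 3, 4, positive = "alive")
#' metric_report(m)
#' @export
metric_report <- function(m, level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$t < 1) stop("empty matrix", call. = FALSE)
  if (m$c1 < 1 || m$c2 < 1) {
    stop("both actual classes must be represented for class-conditional metrics",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  add <- function(metric, x, note = "") {
    rows[[length(rows) + 1]] <<- metric_row(metric, x, note)
  }

  add(sprintf("prevalence_%s", m$positive), proportion_ci(m$c1, m$t, level))
  add(sprintf("prevalence_%s", m$negative), proportion_ci(m$c2, m$t, level))
  add("kappa", cohen_kappa(m, level))

  sens <- proportion_ci(m$a, m$c1, level)
  spec <- proportion_ci(m$d, m$c2, level)
  add("sensitivity", sens)
  add("specificity", spec)
  if (m$r1 >= 1) add("ppv", proportion_ci(m$a, m$r1, level))
  else add("ppv", list(estimate = NaN, lower = NaN, upper = NaN), "no predicted positives")
  if (m$r2 >= 1) add("npv", proportion_ci(m$d, m$r2, level))
  else add("npv", list(estimate = NaN, lower = NaN, upper = NaN), "no predicted negatives")

  for (w in c("lr_positive", "lr_negative", "odds_ratio", "relative_risk",
              "diagnostic_odds_ratio", "error_odds_ratio")) {
    r <- ratio_ci(m, w, level)
    add(w, r, if (r$corrected) "zero cell: Haldane-Anscombe 0.5-corrected CI" else "")
  }

  # difference in proportions (a/r1 - c/r2), Wald
  if (m$r1 >= 1 && m$r2 >= 1) {
    p1 <- m$a / m$r1; p2 <- m$c / m$r2
    dp <- p1 - p2
    se_dp <- sqrt(p1 * (1 - p1) / m$r1 + p2 * (1 - p2) / m$r2)
    dp_ci <- list(estimate = dp, lower = dp - z * se_dp, upper = dp + z * se_dp)
    add("difference_in_proportions", dp_ci)
    if (dp != 0) {
      add("nnt", invert_interval(dp, dp_ci$lower, dp_ci$upper),
          if (dp_ci$lower <= 0 && dp_ci$upper >= 0) "interval crosses zero: upper bound infinite" else "")
    } else {
      add("nnt", list(estimate = Inf, lower = NaN, upper = Inf), "zero risk difference")
    }
    add("arr", list(estimate = -dp, lower = -dp_ci$upper, upper = -dp_ci$lower))
    if (p2 > 0) {
      # rrr = arr / (c/r2) = 1 - rr; interval from the rr interval
      rr <- ratio_ci(m, "relative_risk", level)
      add("rrr", list(estimate = 1 - rr$estimate, lower = 1 - rr$upper,
                      upper = 1 - rr$lower))
    } else {
      add("rrr", list(estimate = NaN, lower = NaN, upper = NaN), "baseline risk zero")
    }
  } else {
    for (w in c("difference_in_proportions", "nnt", "arr", "rrr")) {
      add(w, list(estimate = NaN, lower = NaN, upper = NaN), "empty predicted margin")
    }
  }

  # Youden J, delta method
  j <- sens$estimate + spec$estimate - 1
  se_j <- sqrt(sens$estimate * (1 - sens$estimate) / m$c1 +
                 spec$estimate * (1 - spec$estimate) / m$c2)
  j_ci <- list(estimate = j, lower = j - z * se_j, upper = j + z * se_j)
  add("youden_j", j_ci)
  if (j > 0) {
    add("nnd", invert_interval(j, j_ci$lower, j_ci$upper),
        if (j_ci$lower <= 0 && j_ci$upper >= 0) "interval crosses zero: upper bound infinite" else "")
  } else {
    add("nnd", list(estimate = if (j == 0) Inf else NaN, lower = NaN, upper = NaN),
        "Youden J not positive")
  }

  acc <- proportion_ci(m$a + m$d, m$t, level)
  mis <- proportion_ci(m$b + m$c, m$t, level)
  add("accuracy", acc)
  add("misclassification_rate", mis)
  if (mis$estimate > 0) {
    nnm_bounds <- invert_interval(mis$estimate, mis$lower, mis$upper)
    add("nnm", nnm_bounds,
        if (mis$lower <= 0) "interval reaches zero: upper bound infinite" else "")
  } else {
    add("nnm", list(estimate = Inf, lower = 1 / max(mis$upper, .Machine$double.eps),
                    upper = Inf), "perfect accuracy")
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, matrix = m, level = level,
            class = c("metric_report", "data.frame"))
}

#' Look up one metric from a report
#' @param report a `metric_report`.
#' @param metric metric name as in the `metric` column.
#' @return List with `estimate`, `lower`, `upper`.
#' @export
report_metric <- function(report, metric) {
  i <- match(metric, report$metric)
  if (is.na(i)) stop(sprintf("no metric '%s' in report", metric), call. = FALSE)
  list(estimate = report$estimate[i], lower = report$lower[i],
       upper = report$upper[i])
}

#' Render a metric report as a Markdown block
#'
#' Display rounding follows clinical-report convention: 3 decimals for
#' proportions, 2 for ratios, with sign-crossing bounds printed as
#' "infinite". Full precision is retained in the underlying data frame and
#' in JSON serializations.
#'
#' @param report a `metric_report`.
#' @return Character vector of Markdown lines.
#' @export
format_metric_report_md <- function(report) {
  m <- attr(report, "matrix")
  ratios <- c("lr_positive", "lr_negative", "odds_ratio", "relative_risk",
              "diagnostic_odds_ratio", "error_odds_ratio", "nnt", "nnd", "nnm")
  fmt <- function(v, ratio) {
    if (!is.finite(v)) return(if (is.infinite(v)) "infinite" else "undefined")
    sprintf(if (ratio) "%.2f" else "%.3f", v)
  }
  lines <- c(
    sprintf("| Predicted \\\\ Actual | %s | %s | Totals |", m$positive, m$negative),
    "|---|---|---|---|",
    sprintf("| %s | %d (a) | %d (b) | %d (r1) |", m$positive, m$a, m$b, m$r1),
    sprintf("| %s | %d (c) | %d (d) | %d (r2) |", m$negative, m$c, m$d, m$r2),
    sprintf("| Totals | %d (c1) | %d (c2) | %d (t) |", m$c1, m$c2, m$t),
    "",
    "| Metric | Estimate | 95% CI |",
    "|---|---|---|")
  for (i in seq_len(nrow(report))) {
    r <- report$metric[i] %in% ratios
    lines <- c(lines, sprintf("| %s | %s | %s to %s |",
                              report$metric[i], fmt(report$estimate[i], r),
                              fmt(report$lower[i], r), fmt(report$upper[i], r)))
  }
  lines
}

#' Serialize a metric report to JSON
#'
#' Non-finite values are encoded as the strings `"+inf"`, `"-inf"` and
#' `"undefined"` rather than dropped.
#'
#' @param report a `metric_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
metric_report_json <- function(report, path = NULL) {
  enc <- function(v) {
    if (is.nan(v)) "undefined"
    else if (is.infinite(v)) if (v > 0) "+inf" else "-inf"
    else v
  }
  items <- lapply(seq_len(nrow(report)), function(i) {
    x <- list(estimate = enc(report$estimate[i]), lower = enc(report$lower[i]),
              upper = enc(report$upper[i]))
    if (nzchar(report$note[i])) x$note <- report$note[i]
    x
  })
  names(items) <- report$metric
  m <- attr(report, "matrix")
  obj <- list(orientation = list(positive = m$positive, negative = m$negative),
              cells = list(a = m$a, b = m$b, c = m$c, d = m$d),
              level = attr(report, "level"),
              metrics = items)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
  }
}
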