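# The single published confusion matrix (survival-positive orientation)
# whose ledger the metrics module must reproduce at printed precision.
reference_matrix <- function() confusion_matrix(183, 73, 3, 4, positive = "alive")

test_that("the full metric ledger reproduces the published point estimates", {
  rep <- metric_report(reference_matrix())
  est <- function(name) report_metric(rep, name)$estimate

  expect_equal(round(est("prevalence_alive"), 3), 0.707)
  expect_equal(round(est("prevalence_deceased"), 3), 0.293)
  expect_equal(round(est("sensitivity"), 3), 0.984)
  expect_equal(round(est("specificity"), 3), 0.052)
  expect_equal(round(est("ppv"), 3), 0.715)
  expect_equal(round(est("npv"), 3), 0.571)
  expect_equal(round(est("lr_positive"), 3), 1.038)
  expect_equal(round(est("lr_negative"), 3), 0.310)
  expect_equal(round(est("odds_ratio"), 2), 3.34)
  expect_equal(round(est("relative_risk"), 2), 1.67)
  # the DOR equals the cross-product OR algebraically at full precision
  # (computing it from 3-decimal sensitivity/specificity instead gives 3.373)
  expect_equal(round(est("diagnostic_odds_ratio"), 2), 3.34)
  expect_equal(round(est("difference_in_proportions"), 3), 0.286)
  expect_equal(round(est("nnt"), 2), 3.49)
  expect_equal(round(est("arr"), 3), -0.286)
  expect_equal(round(est("rrr"), 3), -0.668)
  expect_equal(round(est("youden_j"), 3), 0.036)
  expect_equal(round(est("nnd"), 1), 27.9)
  expect_equal(round(est("kappa"), 3), 0.049)
  expect_equal(round(est("accuracy"), 3), 0.711)
  expect_equal(round(est("misclassification_rate"), 3), 0.289)
  expect_equal(round(est("nnm"), 2), 3.46)
  # error odds ratio follows its ledger formula ab/cd exactly
  expect_equal(est("error_odds_ratio"), 183 * 73 / (3 * 4), tolerance = 1e-12)
  # sign-crossing inversions report an infinite upper bound
  expect_equal(report_metric(rep, "nnt")$upper, Inf)
  expect_equal(report_metric(rep, "nnd")$upper, Inf)
})

test_that("metric algebraic identities hold on random matrices", {
  set.seed(909)
  for (i in 1:25) {
    m <- random_matrix()
    rep <- metric_report(m)
    acc <- report_metric(rep, "accuracy")$estimate
    mis <- report_metric(rep, "misclassification_rate")$estimate
    expect_equal(acc + mis, 1, tolerance = 1e-12)
    sens <- report_metric(rep, "sensitivity")$estimate
    spec <- report_metric(rep, "specificity")$estimate
    expect_equal(report_metric(rep, "youden_j")$estimate, sens + spec - 1,
                 tolerance = 1e-12)
    # DOR as odds-of-sensitivity over odds-of-false-positive-rate equals
    # the cross-product odds ratio whenever no cell is zero
    if (all(c(m$a, m$b, m$c, m$d) > 0)) {
      dor <- (sens / (1 - sens)) / ((1 - spec) / spec)
      expect_equal(report_metric(rep, "diagnostic_odds_ratio")$estimate, dor,
                   tolerance = 1e-9)
      expect_equal(report_metric(rep, "odds_ratio")$estimate, dor,
                   tolerance = 1e-9)
    }
    j <- report_metric(rep, "youden_j")$estimate
    if (j > 0) {
      expect_equal(report_metric(rep, "nnd")$estimate, 1 / j, tolerance = 1e-12)
    }
    if (acc < 1) {
      expect_equal(report_metric(rep, "nnm")$estimate, 1 / (1 - acc),
                   tolerance = 1e-9)
    }
    dp <- report_metric(rep, "difference_in_proportions")$estimate
    expect_equal(report_metric(rep, "arr")$estimate, -dp, tolerance = 1e-12)
  }
})

test_that("swapping the positive class maps the metrics to their duals", {
  set.seed(910)
  for (i in 1:15) {
    m <- random_matrix()
    r1 <- metric_report(m)
    r2 <- metric_report(flip_orientation(m))
    expect_equal(report_metric(r2, "sensitivity")$estimate,
                 report_metric(r1, "specificity")$estimate)
    expect_equal(report_metric(r2, "specificity")$estimate,
                 report_metric(r1, "sensitivity")$estimate)
    expect_equal(report_metric(r2, "ppv")$estimate,
                 report_metric(r1, "npv")$estimate)
    expect_equal(report_metric(r2, "npv")$estimate,
                 report_metric(r1, "ppv")$estimate)
    # the cross-product ratio is invariant under a full class swap (both
    # margins relabel), while the likelihood ratios invert into each other
    or1 <- report_metric(r1, "odds_ratio")$estimate
    or2 <- report_metric(r2, "odds_ratio")$estimate
    if (is.finite(or1)) expect_equal(or2, or1, tolerance = 1e-9)
    lrp1 <- report_metric(r1, "lr_positive")$estimate
    lrn2 <- report_metric(r2, "lr_negative")$estimate
    if (is.finite(lrp1) && lrp1 > 0) {
      expect_equal(lrn2, 1 / lrp1, tolerance = 1e-9)
    }
  }
})

test_that("a perfect classifier produces the boundary ledger", {
  m <- confusion_matrix(50, 0, 0, 50, positive = "deceased")
  rep <- metric_report(m)
  for (nm in c("sensitivity", "specificity", "accuracy", "kappa", "youden_j")) {
    expect_equal(report_metric(rep, nm)$estimate, 1, tolerance = 1e-12)
  }
  expect_equal(report_metric(rep, "misclassification_rate")$estimate, 0)
  expect_equal(report_metric(rep, "nnm")$estimate, Inf)
})

test_that("kappa follows its agreement formula and transposition invariance", {
  m <- reference_matrix()
  k <- cohen_kappa(m)
  p_o <- 187 / 263
  p_e <- 48155 / 69169
  expect_equal(k$estimate, (p_o - p_e) / (1 - p_e), tolerance = 1e-12)
  expect_equal(round(k$estimate, 3), 0.049)

  # transposing the matrix (swapping rater roles) leaves kappa unchanged
  mt <- confusion_matrix(m$a, m$c, m$b, m$d, positive = m$positive)
  expect_equal(cohen_kappa(mt)$estimate, k$estimate, tolerance = 1e-12)

  # perfect agreement and independence structure
  expect_equal(cohen_kappa(confusion_matrix(30, 0, 0, 20))$estimate, 1)
  # cells proportional to margin products: observed = chance agreement
  ind <- confusion_matrix(40, 10, 40, 10)
  expect_equal(cohen_kappa(ind)$estimate, 0, tolerance = 1e-12)
})

test_that("Wilson intervals behave at the edges and match the published mortality CI", {
  edge <- proportion_ci(0, 10)
  expect_equal(edge$lower, 0)
  expect_gt(edge$upper, 0)

  mort <- proportion_ci(77, 263)
  expect_equal(round(mort$lower, 2), 0.24)
  expect_equal(round(mort$upper, 2), 0.35)
  expect_equal(round(100 * mort$lower, 1), 24.1)
  expect_equal(round(100 * mort$upper, 1), 35.0)

  # interval always contains the point estimate and stays in [0, 1]
  set.seed(22)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- proportion_ci(k, n)
    expect_true(ci$lower <= k / n && k / n <= ci$upper)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
  }

  # cross-check against the score-test interval of an established routine
  ref <- prop.test(77, 263, correct = FALSE)
  expect_equal(c(mort$lower, mort$upper), unname(ref$conf.int),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Wilson coverage is near nominal under binomial simulation", {
  n <- 263; p <- 0.3; reps <- 10000
  set.seed(33)
  ks <- rbinom(reps, n, p)
  z <- qnorm(0.975)
  centre <- (ks + z^2 / 2) / (n + z^2)
  half <- z * sqrt(ks * (n - ks) / n + z^2 / 4) / (n + z^2)
  covered <- mean(centre - half <= p & p <= centre + half)
  # independent recomputation above; the package must agree case by case
  idx <- sample(reps, 50)
  for (i in idx) {
    ci <- proportion_ci(ks[i], n)
    expect_equal(ci$lower, max(0, centre[i] - half[i]), tolerance = 1e-12)
    expect_equal(ci$upper, min(1, centre[i] + half[i]), tolerance = 1e-12)
  }
  expect_gte(covered, 0.93)
})

test_that("ratio intervals follow the log-delta formulas and the zero-cell policy", {
  m <- reference_matrix()
  or <- ratio_ci(m, "odds_ratio")
  se <- sqrt(1 / 183 + 1 / 73 + 1 / 3 + 1 / 4)
  expect_false(or$corrected)
  expect_true(or$lower < 3.34 && or$upper > 3.34)
  expect_equal(or$lower, exp(log(3.342466) - qnorm(0.975) * se), tolerance = 1e-4)

  # symmetric matrix: OR = 1 with a log-symmetric interval
  sym <- confusion_matrix(8, 8, 8, 8)
  s <- ratio_ci(sym, "odds_ratio")
  expect_equal(s$estimate, 1)
  expect_equal(s$lower * s$upper, 1, tolerance = 1e-10)

  # zero cell: non-finite estimate, finite corrected interval, flagged
  zc <- confusion_matrix(20, 0, 5, 15)
  r <- ratio_ci(zc, "odds_ratio")
  expect_true(r$corrected)
  expect_true(is.infinite(r$estimate))
  corr_est <- (20.5 / 0.5) / (5.5 / 15.5)
  corr_se <- sqrt(1 / 20.5 + 1 / 0.5 + 1 / 5.5 + 1 / 15.5)
  expect_equal(r$lower, exp(log(corr_est) - qnorm(0.975) * corr_se),
               tolerance = 1e-10)
  expect_true(is.finite(r$lower) && is.finite(r$upper))
})

test_that("undefined metrics are reported with reasons, never dropped", {
  rep <- metric_report(confusion_matrix(0, 0, 10, 10, positive = "deceased"))
  expect_true(all(c("ppv", "nnt", "arr", "rrr") %in% rep$metric))
  expect_true(is.nan(report_metric(rep, "ppv")$estimate))
  expect_match(rep$note[rep$metric == "ppv"], "no predicted positives")
  expect_error(metric_report(confusion_matrix(5, 0, 3, 0)), "both actual classes")
})

test_that("JSON serialization encodes non-finite values explicitly", {
  rep <- metric_report(reference_matrix())
  js <- jsonlite::fromJSON(metric_report_json(rep))
  expect_equal(js$metrics$nnt$upper, "+inf")
  expect_equal(js$cells$a, 183)
  expect_equal(js$orientation$positive, "alive")
  md <- format_metric_report_md(rep)
  expect_true(any(grepl("infinite", md)))
  expect_true(any(grepl("\\| sensitivity \\| 0.984 \\|", md)))
})
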