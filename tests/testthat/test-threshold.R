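test_that("threshold classification matches exhaustive per-record counting", {
  toy <- mews_cohort(score = c(0, 2, 2, 5), outcome = c(0, 1, 0, 1))
  for (T in 0:6) {
    m <- classification_at_threshold(toy, T)
    pred <- toy$score >= T
    expect_equal(m$a, sum(pred & toy$outcome == 1))
    expect_equal(m$b, sum(pred & toy$outcome == 0))
    expect_equal(m$c, sum(!pred & toy$outcome == 1))
    expect_equal(m$d, sum(!pred & toy$outcome == 0))
    expect_equal(m$t, 4)
  }
})

test_that("reference-cohort classification reproduces the published rows", {
  coh <- sicu_cohort()
  m3 <- classification_at_threshold(coh, 3)
  expect_equal(c(m3$a, m3$d, m3$b, m3$c), c(44, 113, 73, 33))
  m0 <- classification_at_threshold(coh, 0)
  expect_equal(c(m0$a, m0$b, m0$d, m0$c), c(77, 186, 0, 0))
})

test_that("threshold scan rows are internally consistent and correctly bounded", {
  coh <- sicu_cohort()
  scan <- threshold_scan(coh)
  row2 <- scan[scan$threshold == 2, ]
  expect_equal(round(row2$sensitivity_pct, 1), 81.8)
  expect_equal(round(row2$one_minus_specificity_pct, 1), 64.5)

  # bottom threshold always predicts everyone positive
  bottom <- scan[scan$threshold == 0, ]
  expect_equal(bottom$sensitivity_pct, 100)
  expect_equal(bottom$one_minus_specificity_pct, 100)
  # sensitivity non-increasing in threshold; margins constant
  expect_true(all(diff(scan$sensitivity_pct) >= 0))  # rows are descending in T
  expect_true(all(scan$tp + scan$fn == sum(coh$outcome)))
  expect_true(all(scan$tp + scan$tn + scan$fp + scan$fn == nrow(coh)))

  set.seed(404)
  rc <- random_cohort(n = 80)
  rscan <- threshold_scan(rc)
  for (i in seq_len(nrow(rscan))) {
    m <- classification_at_threshold(rc, rscan$threshold[i])
    expect_equal(rscan$sensitivity_pct[i], 100 * m$a / m$c1)
    expect_equal(rscan$one_minus_specificity_pct[i], 100 * m$b / m$c2)
  }

  # one death at 5, one survivor at 0: the top threshold is perfect
  tiny <- mews_cohort(score = c(5, 0), outcome = c(1, 0))
  tscan <- threshold_scan(tiny)
  expect_equal(tscan$sensitivity_pct[tscan$threshold == 5], 100)
  expect_equal(tscan$one_minus_specificity_pct[tscan$threshold == 5], 0)
})

test_that("cut-point selection is the argmax with ties going to the higher threshold", {
  coh <- sicu_cohort()
  sel <- select_cutpoint(threshold_scan(coh))
  expect_equal(sel$threshold, 3)
  # exact fraction 44/77 - 73/186 = 17.90%; the published starred cell 17.8
  # is the difference of the two rounded columns
  expect_equal(sel$youden_diff_pct, 100 * (44 / 77 - 73 / 186), tolerance = 1e-12)

  # perfectly separated toy cohort: difference 100 at the separating threshold
  sep <- mews_cohort(score = c(0, 1, 6, 7), outcome = c(0, 0, 1, 1))
  ssel <- select_cutpoint(threshold_scan(sep))
  expect_equal(ssel$youden_diff_pct, 100)
  expect_true(ssel$threshold %in% 2:6)

  # linear-search oracle on random scans, and explicit tie handling
  set.seed(505)
  for (i in 1:10) {
    rc <- random_cohort(n = 60)
    scan <- threshold_scan(rc)
    sel <- select_cutpoint(scan)
    best <- max(scan$youden_diff_pct)
    expect_equal(sel$youden_diff_pct, best)
    expect_equal(sel$threshold, max(scan$threshold[scan$youden_diff_pct == best]))
  }
})

test_that("probability-rule classification reproduces the published confusion matrix", {
  coh <- sicu_cohort()
  fit <- fit_logistic(coh)
  m <- classification_at_probability(fit, coh, p_cut = 0.5)
  expect_equal(m$positive, "alive")
  expect_equal(c(m$a, m$b, m$c, m$d), c(183, 73, 3, 4))
  expect_equal(m$r2, 7)
  expect_equal(c(m$r1, m$c1, m$c2, m$t), c(256, 186, 77, 263))

  # p_cut = 0 predicts death for everyone
  m0 <- classification_at_probability(fit, coh, p_cut = 0)
  expect_equal(c(m0$a, m0$b), c(0, 0))
  expect_equal(m0$c, 186)
  expect_equal(m0$d, 77)
})

test_that("probability rule is equivalent to a score threshold under a rising fit", {
  set.seed(606)
  coh <- random_cohort(n = 120)
  fit <- fit_logistic(coh)
  expect_gt(fit$beta1, 0)  # the generating link rises in score
  for (p_cut in c(0.2, 0.35, 0.5, 0.65)) {
    m_prob <- classification_at_probability(fit, coh, p_cut)
    # smallest score whose fitted probability exceeds the cut
    s_all <- 0:(max(coh$score) + 1)
    s_cut <- min(s_all[predicted_probability(fit, s_all) > p_cut],
                 max(coh$score) + 1)
    m_score <- classification_at_threshold(coh, s_cut)
    fp <- flip_orientation(m_prob)
    expect_equal(c(fp$a, fp$b, fp$c, fp$d),
                 c(m_score$a, m_score$b, m_score$c, m_score$d))
  }
})

test_that("orientation flip swaps the roles of the two classes coherently", {
  m <- confusion_matrix(183, 73, 3, 4, positive = "alive")
  f <- flip_orientation(m)
  expect_equal(f$positive, "deceased")
  expect_equal(c(f$a, f$b, f$c, f$d), c(4, 3, 73, 183))
  ff <- flip_orientation(f)
  expect_equal(c(ff$a, ff$b, ff$c, ff$d), c(m$a, m$b, m$c, m$d))
})

test_that("dichotomized cut-point model reproduces the published summary", {
  coh <- sicu_cohort()
  d <- dichotomized_model(coh, 3)
  expect_equal(round(d$odds_ratio$estimate, 1), 2.1)
  expect_equal(round(d$relative_risk$estimate, 1), 1.7)
  expect_equal(round(d$chi_square, 1), 7.0)
  expect_equal(round(d$p_value, 4), 0.0080)
  expect_equal(round(d$misclassification$estimate, 2), 0.40)

  # misclassification equals 1 - accuracy of the same matrix
  acc <- (d$matrix$a + d$matrix$d) / d$matrix$t
  expect_equal(d$misclassification$estimate, 1 - acc)

  expect_error(dichotomized_model(coh, 99), "non-empty")
})
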