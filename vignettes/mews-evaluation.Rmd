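---
title: "Evaluating an early-warning score as a mortality predictor: methods"
author: "mewseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an early-warning score as a mortality predictor: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mewseval)
```

## The problem

The Modified Early Warning Score (MEWS) sums banded penalty points over five
bedside measurements — heart rate, respiratory rate, systolic blood pressure,
temperature, and AVPU consciousness level — into a single integer intended to
flag ward patients at risk of deterioration. `mewseval` implements the full
statistical evaluation of such a score as a prognostic marker for in-hospital
mortality in a cohort of patients undergoing unplanned escalation of care to
a surgical ICU: one score per patient at bedside evaluation, one binary vital
status, and the question of whether the score discriminates and classifies
well enough to be clinically usable.

The package ships the cumulative threshold cross-classification table of a
published 263-patient reference cohort (77 deaths). Because that table's
true-positive and false-positive columns are exact cumulative counts under
the rule "predict death iff score >= T", the entire per-patient dataset is
recoverable by differencing adjacent rows; `sicu_cohort()` performs the
reconstruction, and every downstream result in this vignette is computed from
it at run time.

## Cohort reconstruction

For integer scores s, deaths(s) = TP(s) − TP(s+1) and survivors(s) =
FP(s) − FP(s+1), with the cumulative counts above the maximum threshold taken
as zero. `invert_cumulative_table()` applies this differencing after checking
the table's invariants (constant class margins, monotone cumulative counts,
consecutive thresholds down to 0); `cumulate_counts()` is its exact inverse,
and the round trip is property-tested on random tables. Expansion to
per-patient records uses a fixed order (ascending score, deceased before
alive) with sequential identifiers, so fixtures are byte-reproducible.

```{r}
counts <- invert_cumulative_table(sicu_threshold_table())
counts
```

## The prognostic model

Mortality is modelled by univariable logistic regression,
logit P(death) = beta0 + beta1 * score, fitted by the package's own
Newton–Raphson maximum-likelihood routine (`fit_logistic()`), not by a call
to a packaged GLM fitter — the fit itself is part of what the package
re-implements, and `stats::glm` serves only as an independent cross-check in
the test suite (agreement to 1e-6 on random cohorts). Records are aggregated
to per-score sufficient statistics first, so one Newton iteration costs
O(number of distinct scores); convergence is declared when the
log-likelihood changes by less than 1e-10 (at most 100 iterations, with step
halving as a safeguard — the two-parameter problem is concave and in
practice converges in a handful of steps).

Model-level summaries follow the conventional evaluation set:

* whole-model likelihood-ratio statistic, chi-square = 2(LL_full − LL_null)
  on 1 df;
* per-unit odds ratio exp(beta1) with a Wald interval on the log-odds scale;
* the concordance index (C-statistic) of score for death, ties credited one
  half, computed by count arithmetic over the score distribution and tested
  to equal O(n^2) pair enumeration; its interval is Hanley–McNeil;
* fitted per-score mortality probabilities.

Complete separation makes the likelihood unbounded; it is detected (by class
score ranges before fitting, and by a diverged slope |beta1| > 15 after) and
raised as an error, never returned as a silently diverged fit. No Firth-type
correction is attempted.

```{r}
coh <- sicu_cohort()
fit <- fit_logistic(coh)
model_summary(fit, coh)
```

## Threshold analysis and cut-point selection

`threshold_scan()` tabulates the rule "predict death iff score >= T" at every
threshold from the maximum observed score down to 0 (deceased-positive
orientation) and reports sensitivity, 1 − specificity and their difference in
percent. `select_cutpoint()` returns the argmax of that difference — the
threshold-scan analogue of the Youden index — breaking ties toward the higher
(more specific) threshold; no tie occurs in the reference cohort, so the
tie rule is unconstrained by it.

The published confusion-matrix view of this cohort is reproduced by a
*fitted-probability* rule: predict death iff the model's fitted probability
exceeds 0.5 (`classification_at_probability()`). The source never states the
rule behind its matrix, but the inference is forced by count consistency:
exactly 7 patients are predicted deceased, and the only scores with fitted
probability above one half (scores 7 and 8) hold exactly 7 patients. This is
recorded as an interpretive decision. The emitted matrix uses the published
table's survival-positive labelling, with the orientation carried as explicit
metadata and `flip_orientation()` mapping to the conventional
deceased-positive view; a full class swap exchanges sensitivity with
specificity and PPV with NPV, and maps the likelihood ratios to each other's
reciprocals, while the cross-product odds ratio is invariant.

```{r}
scan <- threshold_scan(coh, fit)
select_cutpoint(scan)
classification_at_probability(fit, coh, p_cut = 0.5)
```

`dichotomized_model()` re-analyzes the cohort split at the selected cut:
cross-product odds ratio, relative risk, the LR chi-square of the logistic
fit on the binary indicator, and the misclassification rate of the rule.

## The metric ledger

`metric_report()` computes the complete classical 2x2 ledger from one
oriented matrix: prevalences, kappa, sensitivity, specificity, predictive
values, likelihood ratios, odds/risk ratios, diagnostic and error odds
ratios, difference in proportions, NNT, absolute and relative risk
reduction, Youden J, number needed to diagnose, accuracy, misclassification
rate, and number needed to misdiagnose. Point estimates are the substantive
output. Interval methods are deliberately standard choices, made once:

* Wilson score intervals for all simple proportions (well-behaved at small
  counts; the interval is clamped to contain the point estimate against
  floating-point rounding at k = 0 or k = n);
* log-scale delta-method intervals for ratio measures, with the
  Haldane–Anscombe 0.5 correction applied to the interval only when a cell
  is zero, and flagged;
* the large-sample asymptotic interval for kappa and a delta-method interval
  for Youden J;
* NNT/NND/NNM intervals invert the bounds of the underlying difference; an
  interval whose difference crosses zero has an infinite upper bound,
  reported explicitly (rendered "infinite" in the Markdown view, `"+inf"` in
  JSON) — undefined metrics carry a reason code and are never dropped.

Two ledger caveats, both verified numerically: the diagnostic odds ratio
equals the cross-product odds ratio algebraically, so a value computed from
rounded sensitivity/specificity will differ in the third decimal; and the
error odds ratio is implemented exactly as its formula
[Se/(1−Se)]/[Sp/(1−Sp)] = ab/cd, which on the reference matrix gives
1113.25.

## Bootstrap internal validation

`bootstrap_whole_model()` resamples n patients with replacement
(unstratified), refits the model, and records the LR chi-square per cycle;
the 95% interval is the empirical percentile interval (the plainest reading
of a reported "CI range"; no BCa correction). Resamples that cannot be
fitted — a single outcome class, a single score, separation — are counted
and excluded, never substituted. All randomness flows from the caller's
seed through a generator local to the call, so results are reproducible
bit-for-bit; more than 10% failures raises a warning.

## The synthetic-cohort generator

`generate_cohort()` draws scores i.i.d. from a categorical distribution over
0..S_max and outcomes from the logistic link — exactly the data-generating
frame the analysis assumes. The distribution is categorical rather than
parametric because empirical score frequencies are irregular;
`sicu_reference_spec()` returns the spec whose frequencies and link
parameters equal those of the reconstructed reference cohort, so simulated
cohorts match the study conditions (n = 263, scores 0–8, ~29% mortality).
`generate_vitals_cohort()` additionally emits, for each patient, a bedside
vitals row that scores exactly to the drawn total under a given banded
scoring table: components are visited in a fixed order, each takes the
smallest point value that keeps the remainder achievable, and the first
matching band's midpoint is the measurement — fully deterministic.

What the generator does *not* emulate: correlated vitals, repeated measures
or deterioration trajectories, measurement error in scoring, or informative
missingness. Passing tests therefore demonstrate statistical correctness of
the pipeline under the assumed frame, not robustness of MEWS itself in messy
ward data.

The scoring-table default ships the widely used published MEWS banding
(half-open [lo, hi) bands, temperature in Celsius, AVPU map); the reference
study names the five components but prints no band edges, so the shipped
config is explicitly a configurable default external to it, and no
reference-cohort scoring claim depends on it. Fahrenheit input is rejected,
not converted.

## Problem sizes and numerical choices

The test-suite simulation scales are the package's own choices: parameter
recovery uses cohorts of n = 50,000 over multiple seeds (estimates within 3
standard errors of truth); per-score death-rate convergence uses n = 100,000
(max deviation < 0.02); Wilson coverage uses 10,000 binomial replicates at
n = 263, p = 0.3 (coverage >= 93% at nominal 95%); the bootstrap containment
property uses 30 seeds at 250 cycles in the unit suite and the full
1,000-cycle procedure in the end-to-end checks. The bootstrap's lower
percentile endpoint is intrinsically noisy across seeds, so the sanity
envelope for endpoint agreement is evaluated on seed-averaged endpoints.

## Known limitations

* One score per admission: no repeated-measures or longitudinal handling.
* Univariable modelling only; no adjustment, penalization, or Firth
  correction (separation is an error by design).
* Interval methods are stated choices, not attempts to reverse-engineer the
  reference software's unstated ones; printed interval endpoints are
  therefore not reproduction targets, while point estimates are.
* The C-index interval method (Hanley–McNeil) need not match the one behind
  the reference value's interval.
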