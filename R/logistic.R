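#' Univariable logistic regression of death on score
#'
#' Fits `logit P(death) = beta0 + beta1 * score` by maximum likelihood with
#' the package's own Newton-Raphson routine (exact observed-information
#' Hessian). Records are first aggregated to per-score sufficient statistics,
#' so one iteration costs O(number of distinct scores) regardless of cohort
#' size; this is what keeps thousand-cycle bootstraps cheap. Convergence is
#' declared when the log-likelihood improves by less than `tol` between
#' iterations.
#'
#' Complete separation (a score cut perfectly splitting deaths from
#' survivors) makes the likelihood unbounded; it is detected and raised as an
#' error rather than returned as a silently diverged fit.
#'
#' @param cohort a [mews_cohort] with at least two distinct scores and both
#'   outcomes present.
#' @param tol log-likelihood change tolerance (default 1e-10).
#' @param max_iter maximum Newton iterations (default 100).
#' @return A list of class `mews_logit`: `beta0`, `beta1`, `loglik_full`,
#'   `loglik_null`, `vcov` (2x2 inverse observed information), `converged`,
#'   `n_iter`, `n`, `n_deceased`, plus the per-score aggregation used.
#' @examples
#' fit <- fit_logistic(sicu_cohort())
#' odds_ratio_per_unit(fit)
#' @export
fit_logistic <- function(cohort, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(cohort, "mews_cohort"))
  n <- nrow(cohort)
  nd <- sum(cohort$outcome == 1L)
  if (nd == 0L || nd == n) {
    stop("degenerate data: both outcome classes must be present", call. = FALSE)
  }
  if (length(unique(cohort$score)) < 2L) {
    stop("degenerate data: at least two distinct scores required", call. = FALSE)
  }
  if (max(cohort$score[cohort$outcome == 0L]) < min(cohort$score[cohort$outcome == 1L]) ||
      max(cohort$score[cohort$outcome == 1L]) < min(cohort$score[cohort$outcome == 0L])) {
    stop("complete separation: likelihood is unbounded", call. = FALSE)
  }

  agg <- aggregate_scores(cohort)
  s <- agg$score; m <- agg$n; d <- agg$deaths

  p0 <- nd / n
  loglik_null <- nd * log(p0) + (n - nd) * log1p(-p0)

  beta <- c(stats::qlogis(p0), 0)
  ll <- logit_loglik(beta, s, m, d)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- beta[1] + beta[2] * s
    mu <- stats::plogis(eta)
    w <- m * mu * (1 - mu)
    grad <- c(sum(d - m * mu), sum(s * (d - m * mu)))
    info <- matrix(c(sum(w), sum(s * w), sum(s * w), sum(s * s * w)), 2, 2)
    step <- solve(info, grad)
    # halve the step until the likelihood does not decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- logit_loglik(beta_new, s, m, d)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { beta_new <- beta; ll_new <- ll; break }
    }
    improved <- ll_new - ll
    beta <- beta_new
    ll <- ll_new
    if (abs(improved) < tol) { converged <- TRUE; break }
  }
  if (abs(beta[2]) > 15) {
    stop("complete or quasi-complete separation: coefficient diverged", call. = FALSE)
  }
  eta <- beta[1] + beta[2] * s
  mu <- stats::plogis(eta)
  w <- m * mu * (1 - mu)
  info <- matrix(c(sum(w), sum(s * w), sum(s * w), sum(s * s * w)), 2, 2)

  structure(list(
    beta0 = beta[1], beta1 = beta[2],
    loglik_full = ll, loglik_null = loglik_null,
    vcov = solve(info), converged = converged, n_iter = iter,
    n = n, n_deceased = nd, scores = agg
  ), class = "mews_logit")
}

aggregate_scores <- function(cohort) {
  s <- sort(unique(cohort$score))
  data.frame(
    score = s,
    n = vapply(s, function(k) sum(cohort$score == k), 0L),
    deaths = vapply(s, function(k) sum(cohort$score == k & cohort$outcome == 1L), 0L)
  )
}

logit_loglik <- function(beta, s, m, d) {
  eta <- beta[1] + beta[2] * s
  # y*eta - log(1 + e^eta), summed with multiplicities
  sum(d * eta - m * log1p(exp(pmin(eta, 30)))) - sum(m * pmax(eta - 30, 0))
}

#' @export
print.mews_logit <- function(x, ...) {
  wt <- whole_model_test(x)
  or <- odds_ratio_per_unit(x)
  cat(sprintf("Logistic fit: logit p = %.4f + %.4f * score  (n = %d, deaths = %d)\n",
              x$beta0, x$beta1, x$n, x$n_deceased))
  cat(sprintf("Whole-model LR chi-square = %.1f (df = 1), p = %.4f\n",
              wt$chi_square, wt$p_value))
  cat(sprintf("Odds ratio per unit = %.1f (95%% CI %.1f to %.1f)\n",
              or$estimate, or$lower, or$upper))
  invisible(x)
}

#' Whole-model likelihood-ratio test
#'
#' Compares the fitted model against the intercept-only model:
#' chi-square = 2 (loglik_full - loglik_null) on 1 degree of freedom.
#'
#' @param fit a converged `mews_logit`.
#' @return List with `chi_square` and `p_value` (upper tail, df = 1).
#' @export
whole_model_test <- function(fit) {
  stopifnot(inherits(fit, "mews_logit"))
  if (!fit$converged) stop("fit did not converge; refusing to test", call. = FALSE)
  chi <- max(0, 2 * (fit$loglik_full - fit$loglik_null))
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Fitted mortality probability at a score
#'
#' @param fit a converged `mews_logit`.
#' @param score integer score(s).
#' @return Probability `plogis(beta0 + beta1 * score)`, vectorized over
#'   `score`.
#' @export
predicted_probability <- function(fit, score) {
  stopifnot(inherits(fit, "mews_logit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  stats::plogis(fit$beta0 + fit$beta1 * score)
}

#' Odds ratio per one-unit score increase
#'
#' Exponentiated slope with a Wald interval on the log-odds scale.
#'
#' @param fit a converged `mews_logit`.
#' @param level confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`.
#' @export
odds_ratio_per_unit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mews_logit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  se <- sqrt(fit$vcov[2, 2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = exp(fit$beta1),
       lower = exp(fit$beta1 - z * se),
       upper = exp(fit$beta1 + z * se))
}

#' Concordance index of score for the death outcome
#'
#' Probability that a randomly chosen deceased patient carries a higher score
#' than a randomly chosen survivor, with tied scores credited one half.
#' Computed by count arithmetic over the per-score aggregation (O(S^2) in the
#' number of distinct scores, not O(n^2) in patients), which equals exhaustive
#' pair enumeration. The confidence interval is the Hanley-McNeil asymptotic
#' interval.
#'
#' @param cohort a [mews_cohort] with both outcome classes present.
#' @param level confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `concordant`, `tied`,
#'   `n_pairs`.
#' @export
concordance_index <- function(cohort, level = 0.95) {
  stopifnot(inherits(cohort, "mews_cohort"))
  nd <- sum(cohort$outcome == 1L)
  na <- sum(cohort$outcome == 0L)
  if (nd == 0L || na == 0L) {
    stop("degenerate data: both outcome classes must be present", call. = FALSE)
  }
  agg <- aggregate_scores(cohort)
  deaths <- agg$deaths
  alive <- agg$n - agg$deaths
  alive_below <- c(0, cumsum(alive))[seq_along(alive)]
  concordant <- sum(deaths * alive_below)
  tied <- sum(deaths * alive)
  n_pairs <- as.numeric(nd) * na
  cstat <- (concordant + 0.5 * tied) / n_pairs

  # Hanley & McNeil (1982) SE
  q1 <- cstat / (2 - cstat)
  q2 <- 2 * cstat^2 / (1 + cstat)
  se <- sqrt((cstat * (1 - cstat) + (nd - 1) * (q1 - cstat^2) +
                (na - 1) * (q2 - cstat^2)) / n_pairs)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = cstat,
       lower = max(0, cstat - z * se), upper = min(1, cstat + z * se),
       concordant = concordant, tied = tied, n_pairs = n_pairs)
}

#' Full model summary
#'
#' Bundles the whole-model test, per-unit odds ratio, concordance index and
#' fitted probability at every observed score, ready for JSON serialization.
#'
#' @param fit a converged `mews_logit`.
#' @param cohort the cohort the model was fitted on.
#' @param level confidence level (default 0.95).
#' @return A list of class `mews_model_summary`.
#' @export
model_summary <- function(fit, cohort, level = 0.95) {
  wt <- whole_model_test(fit)
  or <- odds_ratio_per_unit(fit, level)
  ci <- concordance_index(cohort, level)
  s <- fit$scores$score
  structure(list(
    n = fit$n, n_deceased = fit$n_deceased,
    beta0 = fit$beta0, beta1 = fit$beta1,
    loglik_full = fit$loglik_full, loglik_null = fit$loglik_null,
    chi_square = wt$chi_square, p_value = wt$p_value,
    odds_ratio_per_unit = or, c_index = ci[c("estimate", "lower", "upper")],
    fitted_probability = data.frame(score = s,
                                    probability = predicted_probability(fit, s))
  ), class = "mews_model_summary")
}

#' @export
print.mews_model_summary <- function(x, ...) {
  cat(sprintf("n = %d (%d deceased); logit p = %.4f + %.4f * score\n",
              x$n, x$n_deceased, x$beta0, x$beta1))
  cat(sprintf("Whole-model chi-square = %.1f, p = %.4f\n", x$chi_square, x$p_value))
  cat(sprintf("OR per unit = %.1f (%.1f to %.1f); C-index = %.2f (%.2f to %.2f)\n",
              x$odds_ratio_per_unit$estimate, x$odds_ratio_per_unit$lower,
              x$odds_ratio_per_unit$upper, x$c_index$estimate, x$c_index$lower,
              x$c_index$upper))
  pf <- x$fitted_probability
  cat("Fitted mortality probability (%): ",
      paste(sprintf("%d:%.1f", pf$score, 100 * pf$probability), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
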