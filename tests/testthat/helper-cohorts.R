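# Shared fixtures built in code.

# Small random cohort with both outcome classes and >= 2 distinct scores.
random_cohort <- function(n = 60, s_max = 8) {
  repeat {
    score <- sample(0:s_max, n, replace = TRUE)
    outcome <- rbinom(n, 1, plogis(-1 + 0.25 * score))
    if (length(unique(score)) >= 2 && any(outcome == 1) && any(outcome == 0)) {
      return(mews_cohort(score = score, outcome = outcome))
    }
  }
}

# Random per-score outcome counts over scores 0..s_max.
random_counts <- function(s_max = 6, lambda = 4) {
  new_counts <- data.frame(score = 0:s_max,
                           deaths = rpois(s_max + 1, lambda),
                           survivors = rpois(s_max + 1, lambda))
  mewseval:::new_score_counts(new_counts$score, new_counts$deaths,
                              new_counts$survivors)
}

# Random non-degenerate 2x2 matrix.
random_matrix <- function(max_cell = 40) {
  repeat {
    cells <- sample(0:max_cell, 4, replace = TRUE)
    m <- confusion_matrix(cells[1], cells[2], cells[3], cells[4],
                          positive = "deceased")
    if (m$t >= 2 && m$c1 >= 1 && m$c2 >= 1 && m$r1 >= 1 && m$r2 >= 1) return(m)
  }
}

# Brute-force 2-parameter grid maximization of the Bernoulli log-likelihood,
# independent of the Newton path.
grid_search_logistic <- function(cohort, b0_range = c(-4, 4),
                                 b1_range = c(-3, 3), steps = 3) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * cohort$score
    sum(cohort$outcome * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  width <- c(diff(b0_range), diff(b1_range)) / 2
  for (s in seq_len(steps * 4)) {
    b0s <- seq(centre[1] - width[1], centre[1] + width[1], length.out = 41)
    b1s <- seq(centre[2] - width[2], centre[2] + width[2], length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 5
  }
  list(beta0 = centre[1], beta1 = centre[2], loglik = ll(centre[1], centre[2]))
}
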