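#' Specification of a synthetic cohort
#'
#' A synthetic cohort emulates the statistical frame of a bedside-score
#' mortality study: integer scores drawn i.i.d. from a categorical
#' distribution over 0..S_max, and death simulated from the logistic link
#' `logit P(death) = beta0 + beta1 * score`. This mirrors the structure the
#' analysis assumes (one score per admission, binary vital status) and makes
#' parameter recovery demonstrable; it deliberately does not model
#' correlated vitals or deterioration trajectories.
#'
#' @param n cohort size (>= 1).
#' @param score_distribution probability vector over scores `0:(length-1)`;
#'   must be non-negative and sum to 1.
#' @param beta0,beta1 logistic-link intercept and per-unit slope.
#' @param seed integer seed driving all randomness of [generate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, score_distribution, beta0, beta1, seed) {
  stopifnot(n >= 1, all(score_distribution >= 0),
            abs(sum(score_distribution) - 1) < 1e-12)
  structure(list(n = as.integer(n),
                 score_distribution = as.numeric(score_distribution),
                 beta0 = beta0, beta1 = beta1, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Scores are i.i.d. draws from the spec's categorical distribution; each
#' outcome is Bernoulli with probability `plogis(beta0 + beta1 * score)`.
#' Deterministic under the spec's seed; global random state is saved and
#' restored.
#'
#' @param spec a [cohort_spec].
#' @return A [mews_cohort] of `spec$n` records.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  s_max <- length(spec$score_distribution) - 1L
  score <- (0:s_max)[sample.int(s_max + 1L, spec$n, replace = TRUE,
                                prob = spec$score_distribution)]
  p <- stats::plogis(spec$beta0 + spec$beta1 * score)
  outcome <- as.integer(stats::runif(spec$n) < p)
  mews_cohort(score = score, outcome = outcome)
}

#' Reference spec mirroring the packaged surgical-ICU cohort
#'
#' Returns the [cohort_spec] whose score distribution equals the per-score
#' relative frequencies of the reconstructed reference cohort (mass on
#' scores 0-8) and whose link parameters are the maximum-likelihood
#' estimates of the logistic fit on that cohort. Generated cohorts therefore
#' have the same size, score shape and mortality gradient as the reference
#' study population.
#'
#' @param seed integer seed stored in the spec (default 1).
#' @return A [cohort_spec] with `n = 263`.
#' @export
sicu_reference_spec <- function(seed = 1L) {
  coh <- sicu_cohort()
  counts <- score_counts(coh)
  freq <- (counts$deaths + counts$survivors) / nrow(coh)
  fit <- fit_logistic(coh)
  cohort_spec(n = nrow(coh), score_distribution = freq,
              beta0 = fit$beta0, beta1 = fit$beta1, seed = seed)
}

#' Serialize / read a cohort spec as JSON
#' @param spec a [cohort_spec].
#' @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(x$n, x$score_distribution, x$beta0, x$beta1, x$seed)
}

# Achievable per-component point values and the deterministic decomposition
# of a target total into component points (smallest feasible points assigned
# in fixed component order).
component_points <- function(table) {
  pts <- lapply(table$components, function(b) sort(unique(b$points)))
  pts$avpu <- sort(unique(unname(table$avpu)))
  pts
}

decompose_score <- function(target, point_sets) {
  feasible <- function(k, sets) {
    if (!length(sets)) return(k == 0)
    any(vapply(sets[[1]], function(p) p <= k && feasible(k - p, sets[-1]),
               logical(1)))
  }
  if (!feasible(target, point_sets)) return(NULL)
  chosen <- integer(length(point_sets))
  rem <- target
  for (i in seq_along(point_sets)) {
    for (p in point_sets[[i]]) {
      if (p <= rem && feasible(rem - p, point_sets[-seq_len(i)])) {
        chosen[i] <- p
        rem <- rem - p
        break
      }
    }
  }
  stats::setNames(chosen, names(point_sets))
}

vitals_for_points <- function(points, table) {
  row <- list()
  for (nm in names(table$components)) {
    b <- table$components[[nm]]
    hit <- which(b$points == points[[nm]])[1]   # first band in ascending-lo order
    row[[nm]] <- (b$lo[hit] + b$hi[hit]) / 2    # band midpoint
  }
  avpu_order <- c("Alert", "Voice", "Pain", "Unresponsive")
  row$avpu <- avpu_order[which(table$avpu[avpu_order] == points[["avpu"]])[1]]
  row
}

#' Generate a vitals table realizing a synthetic cohort
#'
#' Draws a cohort from the spec, then emits for every patient a bedside
#' vitals row that scores exactly to the drawn MEWS under the given scoring
#' table. The decomposition of a total into component points is
#' deterministic: components are visited in fixed order (heart rate,
#' respiratory rate, systolic blood pressure, temperature, AVPU), each takes
#' the smallest point value keeping the remainder achievable, and the first
#' matching band's midpoint is used as the measurement.
#'
#' @param spec a [cohort_spec]; every score with positive probability must
#'   be achievable under `table`.
#' @param table a `scoring_table`.
#' @return List with `vitals` (data frame with outcome column) and `cohort`
#'   (the drawn [mews_cohort]).
#' @export
generate_vitals_cohort <- function(spec, table = default_scoring_table()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pts <- component_points(table)
  targets <- which(spec$score_distribution > 0) - 1L
  decomp <- lapply(targets, decompose_score, point_sets = pts)
  bad <- targets[vapply(decomp, is.null, logical(1))]
  if (length(bad)) {
    stop(sprintf("score %d not achievable under the scoring table", bad[1]),
         call. = FALSE)
  }
  names(decomp) <- as.character(targets)
  cohort <- generate_cohort(spec)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- vitals_for_points(decomp[[as.character(cohort$score[i])]], table)
    data.frame(patient_id = cohort$patient_id[i],
               heart_rate = v$heart_rate,
               respiratory_rate = v$respiratory_rate,
               systolic_bp = v$systolic_bp,
               temperature = v$temperature,
               avpu = v$avpu,
               outcome = cohort$outcome[i],
               stringsAsFactors = FALSE)
  })
  list(vitals = do.call(rbind, rows), cohort = cohort)
}
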