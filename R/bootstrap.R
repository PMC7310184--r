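#' Bootstrap internal validation of the whole-model statistic
#'
#' Nonparametric case bootstrap of the univariable logistic model: each cycle
#' resamples n patients with replacement (unstratified), refits the model and
#' records the whole-model likelihood-ratio chi-square. The 95% interval is
#' the empirical percentile interval of the resampled statistics. Resamples
#' where the fit fails (a single outcome class, a single score value, or
#' complete separation) are counted in `n_failed` and excluded, never
#' substituted.
#'
#' All randomness flows from the supplied seed through a generator local to
#' the call; global random state is saved and restored, so the same
#' `(cohort, n_resamples, seed)` always yields an identical result.
#'
#' @param cohort a fittable [mews_cohort].
#' @param n_resamples number of bootstrap cycles (default 1000).
#' @param seed integer seed; mandatory, no implicit global randomness.
#' @param level confidence level for the percentile interval (default 0.95).
#' @return A list of class `mews_bootstrap`: `n_resamples`, `statistics`
#'   (one chi-square per successful resample), `interval`, `seed`,
#'   `n_failed`, `level`.
#' @export
bootstrap_whole_model <- function(cohort, n_resamples = 1000L, seed, level = 0.95) {
  stopifnot(inherits(cohort, "mews_cohort"), n_resamples >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- nrow(cohort)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  stats_out <- numeric(0)
  n_failed <- 0L
  for (i in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- mews_cohort(score = cohort$score[idx], outcome = cohort$outcome[idx])
    chi <- tryCatch(whole_model_test(fit_logistic(boot))$chi_square,
                    error = function(e) NA_real_)
    if (is.na(chi)) n_failed <- n_failed + 1L else stats_out <- c(stats_out, chi)
  }
  if (!length(stats_out)) stop("all bootstrap resamples failed", call. = FALSE)
  if (n_failed > 0.1 * n_resamples) {
    warning(sprintf("%d of %d bootstrap resamples failed", n_failed, n_resamples))
  }
  alpha <- 1 - level
  interval <- unname(stats::quantile(stats_out, c(alpha / 2, 1 - alpha / 2),
                                     type = 7))
  structure(list(
    n_resamples = n_resamples, statistics = stats_out,
    interval = list(lower = interval[1], upper = interval[2]),
    seed = seed, n_failed = n_failed, level = level
  ), class = "mews_bootstrap")
}

#' @export
print.mews_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d cycles (%d failed), seed %d\n",
              x$n_resamples, x$n_failed, x$seed))
  cat(sprintf("%.0f%% percentile interval of whole-model chi-square: %.2f to %.2f\n",
              100 * x$level, x$interval$lower, x$interval$upper))
  invisible(x)
}

#' Serialize a bootstrap result to JSON
#'
#' @param result a `mews_bootstrap`.
#' @param path optional output path.
#' @param include_statistics include the full per-resample statistic vector
#'   (default `FALSE`).
#' @export
bootstrap_json <- function(result, path = NULL, include_statistics = FALSE) {
  obj <- list(n_resamples = result$n_resamples, seed = result$seed,
              n_failed = result$n_failed, level = result$level,
              interval = result$interval)
  if (include_statistics) obj$statistics <- result$statistics
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
  }
}
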