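#' Banded MEWS scoring tables
#'
#' MEWS sums integer penalty points over five bedside components: heart rate
#' (beats/min), respiratory rate (breaths/min), systolic blood pressure
#' (mmHg), temperature (degrees C), and AVPU consciousness level (Alert,
#' Voice, Pain, Unresponsive). Each numeric component is scored by a banded
#' table of half-open intervals `[lo, hi) -> points`; AVPU by an explicit
#' four-entry map. Band edges differ between institutions, so the table is a
#' configuration object: `default_scoring_table()` loads the standard
#' published banding shipped with the package, and `read_scoring_table()`
#' loads any user-supplied JSON config of the same shape.
#'
#' @return A list of class `scoring_table` with elements `components` (named
#'   list of data frames `lo`, `hi`, `points`) and `avpu` (named integer
#'   vector).
#' @export
default_scoring_table <- function() {
  read_scoring_table(
    system.file("extdata", "mews_bands.json", package = "mewseval",
                mustWork = TRUE))
}

#' @rdname default_scoring_table
#' @param path path to a JSON scoring-table config.
#' @export
read_scoring_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(cfg$components, function(b) {
    b <- as.data.frame(b)[c("lo", "hi", "points")]
    b <- b[order(b$lo), , drop = FALSE]
    rownames(b) <- NULL
    b
  })
  avpu <- unlist(cfg$avpu)
  validate_scoring_table(
    structure(list(components = comps, avpu = avpu), class = "scoring_table"))
}

#' @rdname default_scoring_table
#' @param table a `scoring_table`.
#' @export
write_scoring_table <- function(table, path) {
  stopifnot(inherits(table, "scoring_table"))
  jsonlite::write_json(
    list(components = table$components, avpu = as.list(table$avpu)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_scoring_table <- function(table) {
  for (nm in names(table$components)) {
    b <- table$components[[nm]]
    if (any(b$hi <= b$lo)) {
      stop(sprintf("component '%s': empty or inverted band", nm), call. = FALSE)
    }
    if (nrow(b) > 1 && any(abs(b$lo[-1] - b$hi[-nrow(b)]) > 1e-9)) {
      stop(sprintf("component '%s': bands must be contiguous and disjoint", nm),
           call. = FALSE)
    }
    if (!all(b$points %in% 0:3)) {
      stop(sprintf("component '%s': points must be in 0..3", nm), call. = FALSE)
    }
  }
  need <- c("Alert", "Voice", "Pain", "Unresponsive")
  if (!setequal(names(table$avpu), need)) {
    stop("avpu map must have exactly the levels Alert, Voice, Pain, Unresponsive",
         call. = FALSE)
  }
  table
}

#' Score one MEWS component
#'
#' Numeric components are matched to the unique half-open band `[lo, hi)`
#' containing the value; `avpu` values are looked up in the consciousness
#' map. Values outside the covered range are an error, never silently
#' clamped (in particular a Fahrenheit temperature is rejected, not
#' converted).
#'
#' @param value numeric measurement, or AVPU level for `component = "avpu"`.
#' @param component one of `"heart_rate"`, `"respiratory_rate"`,
#'   `"systolic_bp"`, `"temperature"`, `"avpu"`.
#' @param table a `scoring_table`.
#' @return Integer points.
#' @export
score_component <- function(value, component, table = default_scoring_table()) {
  stopifnot(inherits(table, "scoring_table"), length(value) == 1L)
  if (component == "avpu") {
    if (!value %in% names(table$avpu)) {
      stop(sprintf("avpu level '%s' not in {%s}", value,
                   paste(names(table$avpu), collapse = ", ")), call. = FALSE)
    }
    return(as.integer(table$avpu[[value]]))
  }
  b <- table$components[[component]]
  if (is.null(b)) stop(sprintf("unknown component '%s'", component), call. = FALSE)
  value <- as.numeric(value)
  hit <- which(value >= b$lo & value < b$hi)
  if (length(hit) != 1L) {
    stop(sprintf("%s = %g outside covered range [%g, %g)", component, value,
                 min(b$lo), max(b$hi)), call. = FALSE)
  }
  as.integer(b$points[hit])
}

#' Aggregate MEWS for one set of vitals
#'
#' @param heart_rate,respiratory_rate,systolic_bp,temperature numeric vitals
#'   (temperature in degrees C).
#' @param avpu consciousness level: `"Alert"`, `"Voice"`, `"Pain"` or
#'   `"Unresponsive"`.
#' @param table a `scoring_table`.
#' @return Integer total score, the sum of the five component scores.
#' @export
score_mews <- function(heart_rate, respiratory_rate, systolic_bp, temperature,
                       avpu, table = default_scoring_table()) {
  score_component(heart_rate, "heart_rate", table) +
    score_component(respiratory_rate, "respiratory_rate", table) +
    score_component(systolic_bp, "systolic_bp", table) +
    score_component(temperature, "temperature", table) +
    score_component(avpu, "avpu", table)
}

#' Score a vitals table into a cohort
#'
#' @param vitals data frame with columns `patient_id`, `heart_rate`,
#'   `respiratory_rate`, `systolic_bp`, `temperature`, `avpu`, and optionally
#'   `outcome`.
#' @param table a `scoring_table`.
#' @return The input with a `score` column appended; a [mews_cohort] when an
#'   `outcome` column is present.
#' @export
score_vitals <- function(vitals, table = default_scoring_table()) {
  need <- c("patient_id", "heart_rate", "respiratory_rate", "systolic_bp",
            "temperature", "avpu")
  miss <- setdiff(need, names(vitals))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  sc <- vapply(seq_len(nrow(vitals)), function(i) {
    score_mews(vitals$heart_rate[i], vitals$respiratory_rate[i],
               vitals$systolic_bp[i], vitals$temperature[i],
               as.character(vitals$avpu[i]), table)
  }, integer(1))
  if ("outcome" %in% names(vitals)) {
    mews_cohort(score = sc, outcome = vitals$outcome,
                patient_id = vitals$patient_id)
  } else {
    cbind(vitals, score = sc)
  }
}

#' Maximum achievable total under a scoring table
#' @param table a `scoring_table`.
#' @return Integer maximum of [score_mews()] under `table`.
#' @export
scoring_table_max <- function(table = default_scoring_table()) {
  sum(vapply(table$components, function(b) max(b$points), numeric(1))) +
    max(table$avpu)
}
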