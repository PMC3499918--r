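# Deterministic score algebra: reciprocal transforms, z-scores, z-differences,
# log scores and cut-off classification on the two reading-speed scales.

#' Reading-speed scales
#'
#' Reading speed can be expressed on two reciprocal scales: `"time_per_unit"`
#' (seconds per syllable, sec/syll; higher = worse) and `"units_per_time"`
#' (syllables per second, syll/sec; lower = worse). Every score in this
#' package carries an explicit scale tag; mixing scales silently is exactly
#' the mistake the package is designed to expose, so scale mismatches are
#' rejected, never coerced.
#'
#' @format A character vector of the two admissible scale tags.
#' @export
SCALES <- c("time_per_unit", "units_per_time")

match_scale <- function(scale) {
  match.arg(scale, SCALES)
}

#' Return the opposite reading-speed scale
#' @param scale One of [SCALES].
#' @return The other scale tag.
#' @export
opposite_scale <- function(scale) {
  scale <- match_scale(scale)
  if (scale == "time_per_unit") "units_per_time" else "time_per_unit"
}

#' A single reading performance
#'
#' A raw observation: how many syllables were read and how many seconds it
#' took. Both derived rates (sec/syll and syll/sec) follow by division and
#' multiply to 1 exactly (to machine tolerance), which is the hyperbolic
#' relation between the two scales.
#'
#' @param syllables Positive integer count of syllables read.
#' @param seconds Positive elapsed time in seconds.
#' @return An object of class `"reading_performance"`.
#' @examples
#' compute_rates(reading_performance(100, 50)) # 0.5 sec/syll, 2 syll/sec
#' @export
reading_performance <- function(syllables, seconds) {
  if (length(syllables) != 1L || !is.finite(syllables) ||
      syllables < 1 || syllables != round(syllables)) {
    stop("'syllables' must be a single positive integer (got ",
         deparse(substitute(syllables)), " = ", format(syllables), ")")
  }
  if (length(seconds) != 1L || !is.finite(seconds) || seconds <= 0) {
    stop("'seconds' must be a single positive number (got ",
         format(seconds), ")")
  }
  structure(list(syllables = as.integer(syllables), seconds = seconds),
            class = "reading_performance")
}

#' @export
print.reading_performance <- function(x, ...) {
  r <- compute_rates(x)
  cat(sprintf("Reading performance: %d syllables in %g s (%.4g sec/syll, %.4g syll/sec)\n",
              x$syllables, x$seconds, r[["sec_per_syll"]], r[["syll_per_sec"]]))
  invisible(x)
}

#' Derive both rate scores from a performance
#'
#' @param perf A [reading_performance()].
#' @return Named numeric vector with elements `sec_per_syll` and
#'   `syll_per_sec`; their product is 1 within machine tolerance.
#' @export
compute_rates <- function(perf) {
  stopifnot(inherits(perf, "reading_performance"))
  c(sec_per_syll = perf$seconds / perf$syllables,
    syll_per_sec = perf$syllables / perf$seconds)
}

#' Reciprocal transform
#'
#' The map between the two scales: `y = 1/x`. A strictly decreasing
#' involution on the positive reals.
#'
#' @param score Positive numeric vector.
#' @return `1/score`.
#' @export
reciprocal <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)) || any(score <= 0)) {
    stop("'score' must be finite and strictly positive for the reciprocal transform")
  }
  1 / score
}

#' Natural-log score
#'
#' `log(sec/syll)` and `log(syll/sec)` are linearly related (they are exact
#' negatives of one another), so log-transformed scores do not suffer the
#' scale-discordance problem of the raw reciprocal pair.
#'
#' @param score Positive numeric vector.
#' @return `log(score)`.
#' @export
log_score <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)) || any(score <= 0)) {
    stop("'score' must be finite and strictly positive for the log score")
  }
  log(score)
}

#' Normative statistics on one scale
#'
#' Mean and SD of a normative sample on a declared scale. The Mean/SD ratio
#' is the sole parameter governing the z-mapping between scales; it is always
#' recomputed from `mean` and `sd` (see [mean_sd_ratio()]), never stored.
#'
#' @param mean Positive normative mean, in the units of `scale`.
#' @param sd Positive normative standard deviation.
#' @param scale One of [SCALES].
#' @param n Optional normative sample size.
#' @return An object of class `"norm_stats"`.
#' @examples
#' ns <- norm_stats(0.5, 0.1, "time_per_unit")
#' mean_sd_ratio(ns) # 5
#' @export
norm_stats <- function(mean, sd, scale = c("time_per_unit", "units_per_time"),
                       n = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    stop("'mean' must be a single positive number")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("'sd' must be a single positive number")
  }
  if (!is.null(n) && (length(n) != 1L || n < 1 || n != round(n))) {
    stop("'n' must be a single positive integer when given")
  }
  structure(list(mean = mean, sd = sd, scale = scale,
                 n = if (is.null(n)) NULL else as.integer(n)),
            class = "norm_stats")
}

#' Mean/SD ratio of a normative sample
#' @param stats A [norm_stats()].
#' @return `mean/sd`, recomputed on demand.
#' @export
mean_sd_ratio <- function(stats) {
  stopifnot(inherits(stats, "norm_stats"))
  stats$mean / stats$sd
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("Normative stats [%s]: mean %g, SD %g (Mean/SD ratio %.3g)%s\n",
              x$scale, x$mean, x$sd, mean_sd_ratio(x),
              if (is.null(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

#' Diagnostic cut-off
#'
#' Magnitude of the normality cut-off in z-units (conventionally 2: "at
#' least two standard deviations from the age mean"). The pathology
#' direction follows from the scale: high z on time-per-unit (slow reading),
#' low z on units-per-time. A z exactly at the cut-off classifies as
#' pathological (the criterion is read inclusively).
#'
#' @param magnitude Positive cut-off magnitude in z-units, default 2.
#' @return An object of class `"cutoff"`.
#' @export
cutoff <- function(magnitude = 2) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      !is.finite(magnitude) || magnitude <= 0) {
    stop("'magnitude' must be a single positive number of z-units")
  }
  structure(list(magnitude = magnitude), class = "cutoff")
}

#' z-score against normative statistics
#'
#' @param value Numeric score(s) on the same scale as `stats`.
#' @param stats A [norm_stats()].
#' @return `(value - mean)/sd`.
#' @export
z_score <- function(value, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  (value - stats$mean) / stats$sd
}

#' Signed z-change between two measurements of the same child
#'
#' Positive values denote clinical improvement: on the time-per-unit scale
#' improvement means the score went *down* (faster reading), so the change is
#' `z(before) - z(after)`; on the units-per-time scale improvement means the
#' score went *up*, so the change is `z(after) - z(before)`.
#'
#' @param before,after Raw scores on the scale of `stats`.
#' @param stats A [norm_stats()] carrying the scale tag.
#' @return Signed change in z-units, positive = improvement.
#' @examples
#' # the child who improves from 10 to 5 sec/syll against norms N(0.5, 0.1):
#' delta_z(10, 5, norm_stats(0.5, 0.1, "time_per_unit")) # 50 z-units
#' @export
delta_z <- function(before, after, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$scale == "time_per_unit") {
    z_score(before, stats) - z_score(after, stats)
  } else {
    z_score(after, stats) - z_score(before, stats)
  }
}

#' Classify a z-score as normal or pathological
#'
#' Pathological iff `z >= +magnitude` on the time-per-unit scale, or
#' `z <= -magnitude` on the units-per-time scale. The boundary value counts
#' as pathological. Only the two categories are returned; the z itself is
#' carried so that callers can apply their own borderline bands.
#'
#' @param z Numeric z-score.
#' @param scale One of [SCALES]; determines the pathology direction.
#' @param cut A [cutoff()], default magnitude 2.
#' @return An object of class `"classification"` with fields `z`, `category`
#'   (`"normal"` or `"pathological"`) and `scale`.
#' @export
classify <- function(z, scale = c("time_per_unit", "units_per_time"),
                     cut = cutoff(2)) {
  scale <- match.arg(scale)
  stopifnot(inherits(cut, "cutoff"), is.numeric(z), length(z) == 1L,
            is.finite(z))
  pathological <- if (scale == "time_per_unit") {
    z >= cut$magnitude
  } else {
    z <= -cut$magnitude
  }
  structure(list(z = z,
                 category = if (pathological) "pathological" else "normal",
                 scale = scale),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("z = %+.3f on %s: %s\n", x$z, x$scale, x$category))
  invisible(x)
}

#' Read a table of reading performances from CSV
#'
#' Expects a comma-delimited file with a header row and columns `syllables`
#' and `seconds` (an optional `id` column is preserved). Every row is
#' validated against the performance invariants.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `id`, `syllables`, `seconds`,
#'   `sec_per_syll`, `syll_per_sec`.
#' @export
read_performance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("syllables", "seconds")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("performance table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  for (i in seq_len(nrow(df))) {
    # reuse the constructor's validation row by row
    p <- tryCatch(reading_performance(df$syllables[i], df$seconds[i]),
                  error = function(e) {
                    stop("row ", i, " (id ", df$id[i], "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  }
  df$sec_per_syll <- df$seconds / df$syllables
  df$syll_per_sec <- df$syllables / df$seconds
  df[, c("id", "syllables", "seconds", "sec_per_syll", "syll_per_sec")]
}

#' Write classification records as JSON
#'
#' @param x A `"classification"` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(x, path) {
  if (inherits(x, "classification")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "classification")))
  recs <- lapply(x, function(cl) {
    list(z = cl$z, category = cl$category, scale = cl$scale)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
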