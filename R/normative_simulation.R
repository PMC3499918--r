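# The Monte Carlo study: reciprocal-scale normative statistics, the z-score
# mapping between the two scales, the mapping table, cut-off crossing points
# and the diagnostic discrepancy region.

#' Reciprocal-scale normative statistics
#'
#' Mean and SD of the reciprocal-transformed normative distribution,
#' estimated either by Monte Carlo, by numerical quadrature of the
#' positivity-conditioned reciprocal-normal moments, or by an asymptotic
#' series. Standard errors are present only for Monte Carlo estimates with
#' more than one replicate.
#'
#' @param mean,sd Positive mean and SD of the reciprocal-scale distribution.
#' @param source One of `"monte_carlo"`, `"quadrature"`, `"series"`.
#' @param n_effective Total draws behind a Monte Carlo estimate, or `NULL`.
#' @param se_mean,se_sd Replicate standard errors, or `NULL`.
#' @param per_replicate Optional data frame of per-replicate `mean`, `sd`.
#' @return An object of class `"recip_stats"`.
#' @export
recip_stats <- function(mean, sd,
                        source = c("monte_carlo", "quadrature", "series"),
                        n_effective = NULL, se_mean = NULL, se_sd = NULL,
                        per_replicate = NULL) {
  source <- match.arg(source)
  stopifnot(is.numeric(mean), length(mean) == 1L, mean > 0,
            is.numeric(sd), length(sd) == 1L, sd > 0)
  structure(list(mean = mean, sd = sd, source = source,
                 n_effective = n_effective,
                 se_mean = se_mean, se_sd = se_sd,
                 per_replicate = per_replicate),
            class = "recip_stats")
}

#' @export
print.recip_stats <- function(x, ...) {
  cat(sprintf("Reciprocal-scale stats (%s): mean %.6g", x$source, x$mean))
  if (!is.null(x$se_mean)) cat(sprintf(" ± %.2g", x$se_mean))
  cat(sprintf(", SD %.6g", x$sd))
  if (!is.null(x$se_sd)) cat(sprintf(" ± %.2g", x$se_sd))
  cat("\n")
  invisible(x)
}

#' Monte Carlo moments of the reciprocal-transformed normative sample
#'
#' For each replicate, draws a normative sample of `config$n` scores from
#' Normal(mean, sd) (positivity handled per the config policy), transforms
#' every draw by [reciprocal()], and records the empirical mean and SD of
#' the transformed sample. Estimates are averaged over replicates with
#' replicate standard errors.
#'
#' Child seeds are derived deterministically from `config$seed` keyed by
#' (Mean/SD ratio, replicate), so the estimate for a given ratio is
#' reproducible independently of what else was computed, and depends on
#' `(mean, sd)` only through their ratio up to floating-point scaling.
#'
#' @param mean,sd Normative mean and SD on the original scale.
#' @param config A [sim_config()].
#' @return A [recip_stats()] with `source = "monte_carlo"`.
#' @export
reciprocal_stats_mc <- function(mean, sd, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ratio <- mean / sd
  reps <- config$replicates
  per <- data.frame(mean = numeric(reps), sd = numeric(reps),
                    resampled = integer(reps))
  for (i in seq_len(reps)) {
    x <- sample_normative(mean, sd, config,
                          seed = child_seed(config$seed, ratio, i))
    y <- reciprocal(as.numeric(x))
    per$mean[i] <- mean(y)
    per$sd[i] <- stats::sd(y)
    per$resampled[i] <- attr(x, "resample_count")
  }
  recip_stats(mean = mean(per$mean), sd = mean(per$sd),
              source = "monte_carlo",
              n_effective = config$n * reps,
              se_mean = if (reps > 1) stats::sd(per$mean) / sqrt(reps) else NULL,
              se_sd = if (reps > 1) stats::sd(per$sd) / sqrt(reps) else NULL,
              per_replicate = per)
}

# z on the reciprocal scale of the score placed z_x SDs above the mean on
# the original scale, given frozen reciprocal-scale moments (m, s).
# Works with mean = 1 wlog: the mapping depends on the ratio only.
map_z_given_stats <- function(z_x, ratio, m, s) {
  placement <- 1 + z_x / ratio
  (1 / placement - m) / s
}

check_pole <- function(z_x, ratio) {
  if (any(1 + z_x / ratio <= 0)) {
    stop("placement 1 + z/ratio <= 0: a sec/syll score ", format(min(z_x)),
         " SDs from the mean at Mean/SD ratio ", format(ratio),
         " lies at or beyond the pole of the hyperbola (z <= -ratio)")
  }
}

#' Map a z-score from one scale onto the reciprocal scale (Monte Carlo)
#'
#' The score lying `z_x` SDs above the mean of the original-scale normative
#' distribution is transformed by the reciprocal and standardized against
#' the Monte Carlo reciprocal-scale moments of the same normative sample.
#' The mapping depends on the normative sample only through its Mean/SD
#' ratio, so the ratio is the sole distribution parameter.
#'
#' With the original scale sec/syll (time per unit), positive `z_x` means a
#' slow reader and the mapped syll/sec z is negative; e.g. `z_x = +2` at
#' ratio 5 maps to about -1.36.
#'
#' @param z_x z-score on the original scale.
#' @param ratio Mean/SD ratio of the original-scale normative sample.
#' @param config A [sim_config()].
#' @return A list with `z_y` (replicate-averaged estimate), `se` (replicate
#'   standard error, `NULL` if one replicate), and `per_replicate`.
#' @export
map_z <- function(z_x, ratio, config = sim_config()) {
  stopifnot(is.numeric(z_x), length(z_x) == 1L, is.finite(z_x),
            is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  check_pole(z_x, ratio)
  rs <- reciprocal_stats_mc(1, 1 / ratio, config)
  per <- map_z_given_stats(z_x, ratio, rs$per_replicate$mean,
                           rs$per_replicate$sd)
  list(z_y = mean(per),
       se = if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else NULL,
       per_replicate = per)
}

#' Build the z-mapping table over a grid of ratios and z-scores
#'
#' Cell (r, z) holds the reciprocal-scale z equivalent to original-scale
#' z-score `z` when the normative Mean/SD ratio is `r`, estimated by Monte
#' Carlo with per-(ratio, replicate) seed streams; each cell equals the
#' corresponding [map_z()] call exactly.
#'
#' @param ratios Vector of Mean/SD ratios (default spans 3-50). Ratios
#'   outside `[3, 50]` trigger a warning.
#' @param z_values Vector of original-scale z-scores (default 0.5-4).
#' @param config A [sim_config()].
#' @return An object of class `"mapping_table"`: list with matrices
#'   `estimate` and `se` (rows = ratios, columns = z values) and the config.
#' @export
build_mapping_table <- function(ratios = c(3, 4, 5, 6, 8, 10, 15, 20, 30, 50),
                                z_values = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
                                config = sim_config()) {
  if (any(ratios < 3 | ratios > 50)) {
    warning("ratio(s) outside the studied range [3, 50]")
  }
  est <- se <- matrix(NA_real_, length(ratios), length(z_values),
                      dimnames = list(paste0("ratio_", ratios),
                                      paste0("z_", z_values)))
  for (i in seq_along(ratios)) {
    rs <- reciprocal_stats_mc(1, 1 / ratios[i], config)
    for (j in seq_along(z_values)) {
      check_pole(z_values[j], ratios[i])
      per <- map_z_given_stats(z_values[j], ratios[i],
                               rs$per_replicate$mean, rs$per_replicate$sd)
      est[i, j] <- mean(per)
      se[i, j] <- if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else NA_real_
    }
  }
  structure(list(ratios = ratios, z_values = z_values,
                 estimate = est, se = se, config = config),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, digits = 3, ...) {
  cat("Reciprocal-scale z equivalents (rows: Mean/SD ratio; columns: original-scale z)\n")
  print(round(x$estimate, digits))
  invisible(x)
}

#' Write a mapping table to CSV or JSON
#'
#' CSV cells are formatted `"estimate±se"`; the JSON form carries full
#' provenance (grids, config, per-cell estimates and standard errors).
#'
#' @param table A `"mapping_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_csv <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  cells <- matrix(sprintf("%.4f±%.4f", table$estimate, table$se),
                  nrow = nrow(table$estimate))
  df <- data.frame(ratio = table$ratios, cells, stringsAsFactors = FALSE)
  names(df) <- c("ratio", paste0("z_", table$z_values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mapping_csv
#' @export
write_mapping_json <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  out <- list(ratios = table$ratios, z_values = table$z_values,
              estimate = table$estimate, se = table$se,
              config = unclass(table$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Original-scale z at which the mapped z reaches the opposite cut-off
#'
#' The reciprocal-scale moments are estimated once (replicate-aggregated)
#' and frozen, then the equation `mapped z = -magnitude` is solved for the
#' original-scale z by monotone bracketing and bisection (tolerance 1e-6 in
#' z). Freezing the moments keeps the solved function deterministic and
#' strictly monotone; re-simulating inside the solver would make bisection
#' incoherent. Solving the same equation per replicate yields the reported
#' standard error.
#'
#' This z is the upper end of the diagnostic discrepancy region: between the
#' cut-off magnitude and this value a performance is pathological on the
#' original scale but normal on the reciprocal scale. The root is extremely
#' sensitive to the reciprocal-scale SD (the derivative is about
#' `2 ratio / (m - 2 s)^2`), so its Monte Carlo noise is an order of
#' magnitude larger than that of a mapping cell.
#'
#' @param ratio Mean/SD ratio of the original-scale normative sample.
#' @param cut A [cutoff()].
#' @param config A [sim_config()].
#' @return A list with `z_x_star` (root at the frozen aggregated moments),
#'   `se` (from per-replicate roots), and `per_replicate`.
#' @export
crossing_point <- function(ratio, cut = cutoff(2), config = sim_config()) {
  stopifnot(inherits(cut, "cutoff"))
  rs <- reciprocal_stats_mc(1, 1 / ratio, config)
  solve_one <- function(m, s) {
    f <- function(z) map_z_given_stats(z, ratio, m, s) + cut$magnitude
    lo <- cut$magnitude
    hi <- 1000 * ratio
    if (f(lo) <= 0 || f(hi) >= 0) {
      stop("no sign change in bracket [", format(lo), ", ", format(hi),
           "]: the reciprocal-scale cut-off -", format(cut$magnitude),
           " is not attainable at ratio ", format(ratio))
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
  root <- solve_one(rs$mean, rs$sd)
  per <- vapply(seq_len(nrow(rs$per_replicate)), function(i) {
    solve_one(rs$per_replicate$mean[i], rs$per_replicate$sd[i])
  }, numeric(1))
  list(z_x_star = root,
       se = if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else NULL,
       per_replicate = per)
}

#' Diagnostic discrepancy region
#'
#' The interval of original-scale z-scores classified pathological on the
#' original scale but normal on the reciprocal scale:
#' `[magnitude, crossing_point]`.
#'
#' @inheritParams crossing_point
#' @return Named numeric vector `c(lower, upper)`.
#' @export
discrepancy_region <- function(ratio, cut = cutoff(2), config = sim_config()) {
  cp <- crossing_point(ratio, cut, config)
  c(lower = cut$magnitude, upper = cp$z_x_star)
}

#' Moment-based normality summary of a sample and its reciprocal
#'
#' Skewness and excess kurtosis of the sample and of its reciprocal, for
#' judging which of the two scales is closer to normal. No hypothesis test
#' is attached: the summary is descriptive.
#'
#' @param sample Numeric vector of at least 20 positive values.
#' @return A data frame with rows `original` and `reciprocal` and columns
#'   `skewness`, `excess_kurtosis`.
#' @export
distribution_normality <- function(sample) {
  if (length(sample) < 20) stop("'sample' must have at least 20 values")
  if (stats::sd(sample) == 0) stop("degenerate sample: sd = 0")
  if (any(sample <= 0)) stop("'sample' must be strictly positive to compare with its reciprocal")
  data.frame(scale = c("original", "reciprocal"),
             rbind(moment_shape(sample), moment_shape(1 / sample)),
             row.names = NULL)
}

moment_shape <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(skewness = mean((x - m)^3) / m2^1.5,
    excess_kurtosis = mean((x - m)^4) / m2^2 - 3)
}
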