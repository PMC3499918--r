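# Synthetic-data generation: normative samples, deterministic patient
# placement at chosen z positions, and two-group pre/post treatment designs.

#' Simulation configuration
#'
#' Controls every Monte Carlo computation in the package. `n` is the
#' normative sample size per draw (default 20,000, the size of the simulated
#' normative samples studied here); `replicates` independent child seeds are
#' used for every estimate so that a standard error can be reported.
#'
#' Normal draws at low Mean/SD ratios can be non-positive, where the
#' reciprocal is undefined; `positivity_policy = "resample"` (default)
#' redraws any value at or below `epsilon` and records how many redraws were
#' needed, while `"reject_run"` fails the run if any occur. `epsilon`
#' defaults to `mean/1000` of the target distribution at sampling time.
#'
#' @param n Sample size per normative draw (>= 2). Default 20000.
#' @param seed Integer root seed. Child streams are derived deterministically
#'   per (Mean/SD ratio, replicate) so every table cell is independently
#'   reproducible.
#' @param replicates Number of independent replicate seeds (>= 1). Default 10.
#' @param positivity_policy `"resample"` or `"reject_run"`.
#' @param epsilon Lower admissible score bound, or `NULL` for `mean/1000`.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n = 20000L, seed = 1L, replicates = 10L,
                       positivity_policy = c("resample", "reject_run"),
                       epsilon = NULL) {
  positivity_policy <- match.arg(positivity_policy)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("'n' must be a single integer >= 2")
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("'seed' must be a single integer")
  }
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates < 1 || replicates != round(replicates)) {
    stop("'replicates' must be a single integer >= 1")
  }
  if (!is.null(epsilon) && (!is.numeric(epsilon) || length(epsilon) != 1L ||
                            !is.finite(epsilon) || epsilon <= 0)) {
    stop("'epsilon' must be a single positive number or NULL")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 positivity_policy = positivity_policy,
                 epsilon = epsilon),
            class = "sim_config")
}

config_epsilon <- function(config, mean) {
  if (is.null(config$epsilon)) mean / 1000 else config$epsilon
}

# Deterministic child seed for the stream keyed by (ratio, replicate).
# Modular linear mixing; all intermediates stay below 2^53 so the double
# arithmetic is exact, and the result is a valid 32-bit seed.
child_seed <- function(seed, ratio, replicate) {
  m <- 2147483629
  s <- ((seed %% m) + m) %% m
  s <- (s * 48271 + (round(ratio * 1000) %% m)) %% m
  s <- (s * 48271 + replicate) %% m
  as.integer(s)
}

#' Read a simulation configuration from JSON or YAML
#'
#' Accepts a file with any subset of the [sim_config()] field names
#' (`n`, `seed`, `replicates`, `positivity_policy`, `epsilon`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  lst <- read_config_file(path)
  known <- c("n", "seed", "replicates", "positivity_policy", "epsilon")
  unknown <- setdiff(names(lst), known)
  if (length(unknown) > 0L) {
    stop("unknown simulation config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, lst)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Sample a normative distribution of scores
#'
#' Draws `config$n` values from Normal(mean, sd). Draws at or below the
#' positivity bound are handled according to `config$positivity_policy`;
#' under `"resample"` the redraw count is attached as attribute
#' `"resample_count"`. A fixed seed makes the draw bit-reproducible.
#'
#' @param mean,sd Normative mean and SD (positive). A Mean/SD ratio below 3
#'   triggers a warning: such samples put non-negligible normal mass at or
#'   below zero and lie outside the range studied here.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed` (used internally for
#'   replicate child streams).
#' @return Numeric vector of `config$n` positive scores, with attribute
#'   `resample_count` under the resample policy.
#' @export
sample_normative <- function(mean, sd, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("'sd' must be a single positive number")
  }
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    stop("'mean' must be a single positive number")
  }
  eps <- config_epsilon(config, mean)
  if (eps >= mean) stop("'epsilon' (", eps, ") must be below the mean (", mean, ")")
  if (mean / sd < 3) {
    warning("Mean/SD ratio ", format(mean / sd, digits = 3),
            " is below 3, outside the studied range; reciprocal moments are ",
            "dominated by the near-zero tail and will be unstable")
  }
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  x <- stats::rnorm(config$n, mean, sd)
  bad <- x <= eps
  if (config$positivity_policy == "reject_run") {
    if (any(bad)) {
      stop(sum(bad), " draw(s) at or below epsilon = ", format(eps),
           " under the reject_run positivity policy")
    }
    resampled <- 0L
  } else {
    resampled <- 0L
    while (any(bad)) {
      resampled <- resampled + sum(bad)
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x <= eps
    }
  }
  attr(x, "resample_count") <- resampled
  x
}

#' Place a patient at a chosen z position
#'
#' Deterministic inverse of [z_score()]: the raw score lying `z` normative
#' SDs from the mean, `mean + z*sd`.
#'
#' @param z Numeric z position(s).
#' @param stats A [norm_stats()].
#' @return `mean + z*sd`; placements at or below zero are rejected (they
#'   fall beyond the pole of the reciprocal transform).
#' @export
patient_score <- function(z, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  score <- stats$mean + z * stats$sd
  if (any(score <= 0)) {
    stop("placement mean + z*sd = ", format(min(score)),
         " is non-positive: z = ", format(z[which.min(score)]),
         " lies at or beyond the pole of the reciprocal scale ",
         "(z <= -Mean/SD ratio = ", format(-mean_sd_ratio(stats)), ")")
  }
  score
}

#' Simulate a two-group pre/post treatment design
#'
#' Each group's subjects start at that group's baseline z position on the
#' generating scale (plus subject-level Gaussian noise) and gain the group's
#' stated improvement in z-units of the generating scale (plus independent
#' noise on the post score). All scores are kept positive under the
#' config's positivity policy, so both scale versions of every score exist.
#'
#' @param group_sizes Integer vector of length 2, subjects per group.
#' @param stats Generating-scale [norm_stats()].
#' @param baseline_z Length-2 numeric, per-group baseline z positions.
#' @param gain_z Length-2 numeric, per-group true improvements in z-units of
#'   the generating scale (positive = improvement in the scale's own
#'   direction of better performance).
#' @param noise_sd Non-negative subject-level noise SD in raw score units,
#'   applied independently to pre and post.
#' @param config A [sim_config()]; only `seed` and the positivity policy are
#'   used.
#' @return A data frame (class `"pre_post_design"`) with columns `id`,
#'   `group`, `pre`, `post`, and attributes `scale` and `stats`.
#' @export
sample_pre_post <- function(group_sizes, stats, baseline_z, gain_z,
                            noise_sd, config = sim_config()) {
  stopifnot(inherits(stats, "norm_stats"), inherits(config, "sim_config"))
  if (length(group_sizes) != 2L || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes))) {
    stop("'group_sizes' must be two positive integers")
  }
  if (length(baseline_z) != 2L || length(gain_z) != 2L) {
    stop("'baseline_z' and 'gain_z' must each have length 2")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number")
  }
  eps <- config_epsilon(config, stats$mean)
  # gains are expressed in z-units of the generating scale; convert to raw
  # units with the sign that means "better" on that scale
  sgn <- if (stats$scale == "time_per_unit") -1 else 1
  set.seed(config$seed)
  rows <- list()
  id0 <- 0L
  for (g in 1:2) {
    ng <- group_sizes[g]
    base <- patient_score(baseline_z[g], stats)
    target <- base + sgn * gain_z[g] * stats$sd
    if (target <= 0) {
      stop("group ", g, " post-treatment placement ", format(target),
           " is non-positive on the generating scale")
    }
    pre <- draw_positive(ng, base, noise_sd, eps, config$positivity_policy)
    post <- draw_positive(ng, target, noise_sd, eps, config$positivity_policy)
    rows[[g]] <- data.frame(id = id0 + seq_len(ng),
                            group = c("A", "B")[g],
                            pre = pre, post = post,
                            stringsAsFactors = FALSE)
    id0 <- id0 + ng
  }
  out <- do.call(rbind, rows)
  attr(out, "scale") <- stats$scale
  attr(out, "stats") <- stats
  class(out) <- c("pre_post_design", "data.frame")
  out
}

draw_positive <- function(n, mean, sd, eps, policy) {
  if (sd == 0) {
    if (mean <= eps) stop("degenerate score ", format(mean), " at or below epsilon")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= eps
  if (policy == "reject_run" && any(bad)) {
    stop(sum(bad), " design draw(s) at or below epsilon under reject_run")
  }
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= eps
  }
  x
}

#' Write a cohort or design to CSV
#'
#' Long format with columns `id`, `group`, `time`, `score`, `scale`
#' (comma-separated, dot decimal, header row).
#'
#' @param design A `"pre_post_design"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "pre_post_design"))
  scl <- attr(design, "scale")
  long <- rbind(
    data.frame(id = design$id, group = design$group, time = "pre",
               score = design$pre, scale = scl, stringsAsFactors = FALSE),
    data.frame(id = design$id, group = design$group, time = "post",
               score = design$post, scale = scl, stringsAsFactors = FALSE))
  long <- long[order(long$id, match(long$time, c("pre", "post"))), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param scores Numeric vector of normative scores.
#' @param scale Scale tag of the scores.
#' @export
write_cohort_csv <- function(scores, scale, path) {
  scale <- match_scale(scale)
  df <- data.frame(id = seq_along(scores), group = "norm", time = "norm",
                   score = as.numeric(scores), scale = scale)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
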