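# Executable checks of what does and does not survive the reciprocal
# transform: percentile complementarity, rank-sum test invariance, and the
# interaction-term (difference-of-differences) discordance.

#' Midrank percentile of a value within a sample
#'
#' Plotting position `100 * (r - 0.5) / n` where `r` is the midrank of
#' `value` in `sample` (average rank over ties). Under this convention the
#' percentile of `x` in the sample and the percentile of `1/x` in the
#' reciprocal sample sum to exactly 100, which is why percentile-based
#' diagnostic criteria are scale-free: the 5th percentile of syll/sec is the
#' 95th percentile of sec/syll.
#'
#' @param value A single number.
#' @param sample Non-empty numeric vector.
#' @return Percentile in (0, 100).
#' @export
percentile_rank <- function(value, sample) {
  if (length(sample) == 0L) stop("'sample' must be non-empty")
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  n <- length(sample)
  r <- sum(sample < value) + (sum(sample == value) + 1) / 2
  100 * (r - 0.5) / n
}

#' Maximum deviation from the percentile-complement identity
#'
#' For every `x` in a positive sample, computes
#' `|p(x in sample) + p(1/x in reciprocal sample) - 100|` under the midrank
#' convention and returns the maximum. Exactly 0 for any positive sample,
#' ties included (average ranks make the identity exact).
#'
#' @param sample Positive numeric vector.
#' @return Maximum absolute deviation from 100-complementarity.
#' @export
check_percentile_complement <- function(sample) {
  if (any(!is.finite(sample)) || any(sample <= 0)) {
    stop("'sample' must be finite and strictly positive")
  }
  n <- length(sample)
  # midrank percentile of every element at once; rank(ties = "average")
  # equals the midrank #less + (#equal + 1)/2 used by percentile_rank()
  px <- 100 * (rank(sample, ties.method = "average") - 0.5) / n
  py <- 100 * (rank(1 / sample, ties.method = "average") - 0.5) / n
  max(abs(px + py - 100))
}

#' Rank-sum test on both scales
#'
#' Runs the two-sample Wilcoxon rank-sum (Mann-Whitney) test on the raw
#' scores and on their reciprocals. Because the reciprocal reverses the
#' ordering of positive values, the U statistics are complementary
#' (`U_y = n_a * n_b - U_x`) and the two-sided p-values are identical:
#' rank-based group comparisons cannot be affected by the choice of scale.
#'
#' @param group_a,group_b Non-empty positive numeric vectors.
#' @return A list with `U_x`, `U_y`, `p_x`, `p_y`.
#' @export
rank_test_equivalence <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (any(group_a <= 0) || any(group_b <= 0)) {
    stop("scores must be strictly positive")
  }
  tx <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  ty <- suppressWarnings(stats::wilcox.test(1 / group_a, 1 / group_b))
  list(U_x = unname(tx$statistic), U_y = unname(ty$statistic),
       p_x = tx$p.value, p_y = ty$p.value)
}

#' Interaction term of a two-group pre/post design on a chosen scale
#'
#' Transforms every score to the requested scale (taking reciprocals if the
#' design was generated on the other one), computes each subject's gain
#' `post - pre`, and returns mean gain of group A minus mean gain of group
#' B. Equal gains on the generating scale do not stay equal after the
#' reciprocal unless the groups start from the same baseline, which is the
#' discordance this function exposes.
#'
#' @param design A [sample_pre_post()] result.
#' @param scale One of [SCALES]; must be a valid scale tag.
#' @return The difference of mean gains (group A minus group B).
#' @export
interaction_term <- function(design, scale) {
  stopifnot(inherits(design, "pre_post_design"))
  scale <- match_scale(scale)
  pre <- design$pre
  post <- design$post
  if (scale != attr(design, "scale")) {
    pre <- reciprocal(pre)
    post <- reciprocal(post)
  }
  gain <- post - pre
  mean(gain[design$group == "A"]) - mean(gain[design$group == "B"])
}

#' Default configuration for the interaction-flip demonstrator
#'
#' A frozen two-group pre/post scenario in which the two groups receive
#' *identical* improvements in syll/sec z-units but start from very
#' different baselines (z = -4 vs z = -1). On the generating syll/sec scale
#' the interaction is null; after the reciprocal the same data carry a large
#' interaction, so the permutation test is significant on sec/syll and not
#' on syll/sec.
#'
#' @return A named list accepted by [demo_interaction_flip()].
#' @export
default_flip_config <- function() {
  list(group_sizes = c(12L, 12L),
       scale = "units_per_time",
       norm_mean = 2.0,
       norm_sd = 0.4,
       baseline_z = c(-4, -1),
       gain_z = c(1, 1),
       noise_sd = 0.08,
       seed = 20121116L,
       n_perm = 2000L,
       alpha = 0.05)
}

#' Demonstrate a significance flip of the interaction across scales
#'
#' Simulates a two-group pre/post design from `config`, computes the
#' interaction term on both scales, and tests each with a permutation test
#' that reshuffles group labels over subjects' gain scores (the same
#' permutations are used for both scales, so the two p-values are computed
#' on identical resamples). Reports both p-values and whether they straddle
#' `alpha`.
#'
#' @param config A list with fields `group_sizes`, `scale`, `norm_mean`,
#'   `norm_sd`, `baseline_z`, `gain_z`, `noise_sd`, `seed`, `n_perm`,
#'   `alpha`; see [default_flip_config()].
#' @return A list of class `"flip_report"`: per-scale interaction estimates
#'   and permutation p-values, the `flipped` flag, and the config echo.
#' @export
demo_interaction_flip <- function(config = default_flip_config()) {
  need <- c("group_sizes", "scale", "norm_mean", "norm_sd", "baseline_z",
            "gain_z", "noise_sd", "seed", "n_perm", "alpha")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop("flip config is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (config$noise_sd <= 0) {
    stop("'noise_sd' must be positive: with zero noise all permuted ",
         "interaction values are degenerate and the permutation p-value ",
         "is undefined")
  }
  stats_gen <- norm_stats(config$norm_mean, config$norm_sd,
                          scale = config$scale)
  design <- sample_pre_post(config$group_sizes, stats_gen,
                            config$baseline_z, config$gain_z,
                            config$noise_sd,
                            sim_config(seed = config$seed))
  scale_gen <- attr(design, "scale")
  scale_rec <- opposite_scale(scale_gen)
  gains <- cbind(design$post - design$pre,
                 reciprocal(design$post) - reciprocal(design$pre))
  colnames(gains) <- c(scale_gen, scale_rec)
  is_a <- design$group == "A"
  obs <- colMeans(gains[is_a, , drop = FALSE]) -
    colMeans(gains[!is_a, , drop = FALSE])
  n <- nrow(gains)
  na <- sum(is_a)
  set.seed(config$seed + 1L)  # separate stream from the data generation
  exceed <- c(0L, 0L)
  for (b in seq_len(config$n_perm)) {
    idx <- sample.int(n, na)
    perm <- colMeans(gains[idx, , drop = FALSE]) -
      colMeans(gains[-idx, , drop = FALSE])
    exceed <- exceed + (abs(perm) >= abs(obs))
  }
  p <- (1 + exceed) / (config$n_perm + 1)
  names(p) <- colnames(gains)
  sig <- p < config$alpha
  structure(list(
    interaction = as.list(obs),
    p_value = as.list(p),
    p_interaction_x = unname(p[["time_per_unit"]]),
    p_interaction_y = unname(p[["units_per_time"]]),
    flipped = unname(xor(sig[1], sig[2])),
    alpha = config$alpha,
    config = config), class = "flip_report")
}

#' @export
print.flip_report <- function(x, ...) {
  cat("Interaction permutation test on both scales\n")
  for (s in names(x$p_value)) {
    cat(sprintf("  %s: interaction %+0.4g, p = %.4g\n",
                s, x$interaction[[s]], x$p_value[[s]]))
  }
  cat(sprintf("  significance flip at alpha = %g: %s\n",
              x$alpha, if (x$flipped) "YES" else "no"))
  invisible(x)
}

#' Write a flip report as JSON, or per-subject gains as CSV
#'
#' @param report A `"flip_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flip_json <- function(report, path) {
  stopifnot(inherits(report, "flip_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flip_json
#' @param design A [sample_pre_post()] result.
#' @export
write_gains_csv <- function(design, path) {
  stopifnot(inherits(design, "pre_post_design"))
  scale_gen <- attr(design, "scale")
  df <- data.frame(id = design$id, group = design$group,
                   gain_generating = design$post - design$pre,
                   gain_reciprocal = reciprocal(design$post) - reciprocal(design$pre))
  names(df)[3:4] <- paste0("gain_", c(scale_gen, opposite_scale(scale_gen)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
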