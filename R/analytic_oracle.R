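# Non-Monte-Carlo computation of reciprocal-normal moments: adaptive
# quadrature on the positivity-conditioned distribution and a delta-method
# series. Used to validate the simulation engine.

#' Quadrature specification
#'
#' Integration bounds and tolerance for the conditional reciprocal-normal
#' moments. The unconditional mean of 1/Normal does not exist, so the
#' estimand must be conditioned on a positive lower bound. Two bounds play
#' different roles:
#'
#' * `epsilon0 = mean/1000` is where the *simulator* resamples, matching
#'   [sim_config()].
#' * The quadrature's lower bound `epsilon` defaults to the
#'   *sample-resolution quantile*: the `1/(2 n)` tail quantile of the
#'   epsilon0-conditioned normal (with `n = resolution_n`). Below that
#'   quantile lies mass a sample of `n` draws has less than an even chance
#'   of ever visiting, yet — because the integrand `1/x^2` blows up — that
#'   mass dominates `E[1/X^2 | X > epsilon0]` at small Mean/SD ratios.
#'   Conditioning at the resolution quantile makes "quadrature equals Monte
#'   Carlo" a well-posed comparison at the study's sample size.
#'
#' Set `epsilon` explicitly to integrate from any other bound (e.g.
#' `mean/1000` itself) and see the tail sensitivity directly.
#'
#' @param epsilon Lower integration bound, or `NULL` for the
#'   sample-resolution quantile described above.
#' @param upper_sigmas Upper bound is `mean + upper_sigmas * sd` (default 10;
#'   the mass beyond is below any tolerance used here).
#' @param rel_tol Relative tolerance of the adaptive quadrature, default 1e-10.
#' @param resolution_n Sample size defining the resolution quantile,
#'   default 20000.
#' @return An object of class `"quadrature_spec"`.
#' @export
quadrature_spec <- function(epsilon = NULL, upper_sigmas = 10,
                            rel_tol = 1e-10, resolution_n = 20000L) {
  if (!is.null(epsilon) && (!is.numeric(epsilon) || length(epsilon) != 1L ||
                            epsilon <= 0)) {
    stop("'epsilon' must be a single positive number or NULL")
  }
  stopifnot(is.numeric(upper_sigmas), upper_sigmas > 0,
            is.numeric(rel_tol), rel_tol > 0,
            is.numeric(resolution_n), resolution_n >= 2)
  structure(list(epsilon = epsilon, upper_sigmas = upper_sigmas,
                 rel_tol = rel_tol, resolution_n = as.integer(resolution_n)),
            class = "quadrature_spec")
}

quadrature_epsilon <- function(spec, mean, sd) {
  if (!is.null(spec$epsilon)) return(spec$epsilon)
  eps0 <- mean / 1000
  p0 <- stats::pnorm(eps0, mean, sd)
  stats::qnorm(p0 + (1 - p0) / (2 * spec$resolution_n), mean, sd)
}

cond_moment <- function(mean, sd, eps, upper, k, rel_tol) {
  zmass <- tryCatch(
    stats::integrate(function(x) stats::dnorm(x, mean, sd), eps, upper,
                     rel.tol = rel_tol, subdivisions = 2000L),
    error = function(e) stop("quadrature of the normalizing mass failed: ",
                             conditionMessage(e)))
  num <- tryCatch(
    stats::integrate(function(x) x^(-k) * stats::dnorm(x, mean, sd),
                     eps, upper, rel.tol = rel_tol, subdivisions = 2000L),
    error = function(e) stop("quadrature of the order-", k,
                             " reciprocal moment failed: ",
                             conditionMessage(e)))
  if (num$message != "OK") {
    stop("quadrature did not converge (achieved abs error ",
         format(num$abs.error), "): ", num$message)
  }
  num$value / zmass$value
}

#' Conditional reciprocal-normal moments by quadrature
#'
#' `E[1/X | eps < X < upper]` and the corresponding SD for
#' `X ~ Normal(mean, sd)`, by adaptive quadrature of the renormalized
#' density. Deterministic to the spec's tolerance; this is the independent
#' oracle against which the Monte Carlo engine is validated.
#'
#' @param mean,sd Normative mean and SD on the original scale.
#' @param spec A [quadrature_spec()].
#' @return A [recip_stats()] with `source = "quadrature"`.
#' @export
conditional_reciprocal_moments <- function(mean, sd, spec = quadrature_spec()) {
  stopifnot(inherits(spec, "quadrature_spec"),
            is.numeric(mean), mean > 0, is.numeric(sd), sd > 0)
  eps <- quadrature_epsilon(spec, mean, sd)
  if (eps >= mean) stop("integration lower bound ", format(eps),
                        " must be below the mean ", format(mean))
  upper <- mean + spec$upper_sigmas * sd
  m1 <- cond_moment(mean, sd, eps, upper, 1L, spec$rel_tol)
  m2 <- cond_moment(mean, sd, eps, upper, 2L, spec$rel_tol)
  recip_stats(mean = m1, sd = sqrt(m2 - m1^2), source = "quadrature")
}

#' Delta-method series for reciprocal-normal moments
#'
#' Truncated asymptotic expansions in `v = (sd/mean)^2`:
#' `E[1/X] ~ (1/mean)(1 + v + 3 v^2 + 15 v^3 + 105 v^4)` and
#' `E[1/X^2] ~ (1/mean^2)(1 + 3 v + 15 v^2 + 105 v^3 + 945 v^4)`.
#' The series is asymptotic, not convergent: terms eventually grow, so it is
#' only trustworthy at Mean/SD ratios of about 5 and above, and `order`
#' beyond 4 is not offered.
#'
#' @param mean,sd Normative mean and SD on the original scale.
#' @param order Truncation order, an integer in 1..4.
#' @return A [recip_stats()] with `source = "series"`.
#' @export
series_reciprocal_moments <- function(mean, sd, order = 4L) {
  stopifnot(is.numeric(mean), mean > 0, is.numeric(sd), sd > 0)
  if (length(order) != 1L || !order %in% 1:4) {
    stop("'order' must be an integer between 1 and 4")
  }
  v <- (sd / mean)^2
  c1 <- c(1, 3, 15, 105)    # coefficients of v^k in E[1/X]
  c2 <- c(3, 15, 105, 945)  # coefficients of v^k in E[1/X^2]
  k <- seq_len(order)
  m1 <- (1 / mean) * (1 + sum(c1[k] * v^k))
  m2 <- (1 / mean^2) * (1 + sum(c2[k] * v^k))
  recip_stats(mean = m1, sd = sqrt(m2 - m1^2), source = "series")
}

#' Analytic z-mapping via quadrature moments
#'
#' Same mapping as [map_z()] but standardizing against the quadrature
#' moments instead of Monte Carlo estimates: smooth, deterministic, and
#' strictly decreasing in `z_x`.
#'
#' @param z_x z-score(s) on the original scale.
#' @param ratio Mean/SD ratio of the original-scale normative sample.
#' @param spec A [quadrature_spec()].
#' @return Numeric vector of mapped reciprocal-scale z-scores.
#' @export
map_z_analytic <- function(z_x, ratio, spec = quadrature_spec()) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  eps <- quadrature_epsilon(spec, 1, 1 / ratio)
  if (any(1 + z_x / ratio <= eps)) {
    stop("placement 1 + z/ratio = ", format(min(1 + z_x / ratio)),
         " lies at or below the integration bound ", format(eps))
  }
  rs <- conditional_reciprocal_moments(1, 1 / ratio, spec)
  map_z_given_stats(z_x, ratio, rs$mean, rs$sd)
}

#' Write a moments report as JSON
#'
#' @param stats A [recip_stats()].
#' @param spec The [quadrature_spec()] that produced it (echoed verbatim).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_moments_json <- function(stats, spec, path) {
  stopifnot(inherits(stats, "recip_stats"), inherits(spec, "quadrature_spec"))
  out <- list(mean = stats$mean, sd = stats$sd, source = stats$source,
              spec = unclass(spec))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
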