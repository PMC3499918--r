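test_that("midrank percentiles follow the plotting-position formula", {
  expect_equal(percentile_rank(3, c(1, 2, 3, 4, 5)), 50)
  expect_equal(percentile_rank(1, c(1, 2, 3)), 100 * 0.5 / 3)
  # the 5th-percentile value of a rate sample sits at the 95th percentile
  # of the reciprocal sample
  x <- random_positive(199, seed = 13)
  v <- sort(x)[10]
  expect_equal(percentile_rank(v, x) + percentile_rank(1 / v, 1 / x), 100)
  expect_error(percentile_rank(1, numeric(0)), "non-empty")
})

test_that("the percentile-complement identity is exact, ties included", {
  expect_equal(check_percentile_complement(random_positive(500, seed = 17)), 0)
  # hand-enumerated tied case {1, 1, 2}: midranks 1.5, 1.5, 3 on the raw
  # scale and 2.5, 2.5, 1 after the reciprocal, so every pair sums to 100
  expect_equal(check_percentile_complement(c(1, 1, 2)), 0)
  # holds at the normative-sample scale
  big <- as.numeric(sample_normative(1, 0.2, study_config()))
  expect_equal(check_percentile_complement(big), 0)
  expect_error(check_percentile_complement(c(1, -1)), "positive")
})

test_that("rank-sum tests are invariant to the reciprocal transform", {
  r <- rank_test_equivalence(c(1, 2), c(3, 4))
  expect_equal(r$U_x, 0)
  expect_equal(r$U_y, 4)
  expect_equal(r$p_x, r$p_y)
  same <- rank_test_equivalence(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_x, 1)
  expect_equal(same$p_y, 1)
  # property: U complement and identical two-sided p over random cohorts
  for (s in 1:20) {
    set.seed(100 + s)
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    a <- exp(stats::rnorm(na, 0, 0.5))
    b <- exp(stats::rnorm(nb, 0.3, 0.5))
    r <- rank_test_equivalence(a, b)
    expect_equal(r$U_y, na * nb - r$U_x)
    expect_lt(abs(r$p_x - r$p_y), 1e-12)
  }
})

test_that("equal differences on one scale are never equal on the other", {
  # strict convexity witness: y1 < y2 <= y3 < y4 with equal spacings
  set.seed(31)
  for (i in 1:100) {
    y1 <- stats::runif(1, 0.05, 2)
    d <- stats::runif(1, 0.01, 1)
    y3 <- y1 + stats::runif(1, 0, 3)
    expect_gt(1 / y1 - 1 / (y1 + d), 1 / y3 - 1 / (y3 + d) - 1e-15)
    if (y3 > y1) expect_gt(1 / y1 - 1 / (y1 + d), 1 / y3 - 1 / (y3 + d))
  }
})

test_that("interaction terms transform with the scale and negate on relabel", {
  ns <- norm_stats(2, 0.4, "units_per_time")
  d <- sample_pre_post(c(8, 8), ns, baseline_z = c(-4, -1),
                       gain_z = c(1, 1), noise_sd = 0, config = sim_config(seed = 4))
  # equal rate-scale gains: null interaction there, large one after reciprocal
  expect_equal(interaction_term(d, "units_per_time"), 0, tolerance = 1e-12)
  expect_gt(abs(interaction_term(d, "time_per_unit")), 0.5)
  swapped <- d
  swapped$group <- ifelse(d$group == "A", "B", "A")
  expect_equal(interaction_term(swapped, "time_per_unit"),
               -interaction_term(d, "time_per_unit"))
  expect_error(interaction_term(d, "bogus_scale"))
})

test_that("the shipped flip scenario is significant on one scale only", {
  rep1 <- demo_interaction_flip()
  expect_true(rep1$flipped)
  expect_lt(rep1$p_interaction_x, 0.05)
  expect_gt(rep1$p_interaction_y, 0.05)
  # bit-reproducible under its seed
  rep2 <- demo_interaction_flip()
  expect_identical(rep1$p_value, rep2$p_value)
  expect_identical(rep1$interaction, rep2$interaction)
})

test_that("a null scenario does not flip and zero noise is rejected", {
  cfg <- default_flip_config()
  cfg$baseline_z <- c(-2, -2)
  null_rep <- demo_interaction_flip(cfg)
  expect_false(null_rep$flipped)
  expect_gt(null_rep$p_interaction_x, 0.05)
  expect_gt(null_rep$p_interaction_y, 0.05)
  bad <- default_flip_config()
  bad$noise_sd <- 0
  expect_error(demo_interaction_flip(bad), "noise")
  incomplete <- default_flip_config()
  incomplete$gain_z <- NULL
  expect_error(demo_interaction_flip(incomplete), "gain_z")
})

test_that("doubling the noise weakens the interaction evidence", {
  # power monotonicity, majority vote over seeds
  wins <- 0L
  for (s in 1:5) {
    lo <- default_flip_config()
    lo$seed <- 3000 + s
    lo$n_perm <- 500L
    hi <- lo
    hi$noise_sd <- 2 * lo$noise_sd
    p_lo <- demo_interaction_flip(lo)$p_interaction_x
    p_hi <- demo_interaction_flip(hi)$p_interaction_x
    wins <- wins + (p_hi >= p_lo)
  }
  expect_gte(wins, 3L)
})

test_that("flip reports and per-subject gains serialize", {
  rep1 <- demo_interaction_flip()
  js <- withr::local_tempfile(fileext = ".json")
  write_flip_json(rep1, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_true(back$flipped)
  expect_equal(back$p_value$time_per_unit, rep1$p_interaction_x)
  ns <- norm_stats(2, 0.4, "units_per_time")
  d <- sample_pre_post(c(4, 4), ns, c(-2, -1), c(1, 1), 0.05,
                       sim_config(seed = 8))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gains_csv(d, csv)
  gains <- utils::read.csv(csv)
  expect_equal(nrow(gains), 8)
  expect_true(all(c("gain_units_per_time", "gain_time_per_unit") %in%
                    names(gains)))
})
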