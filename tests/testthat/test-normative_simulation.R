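# Frozen quadrature reference values for the reciprocal-normal moments,
# conditioned at the sample-resolution bound (independently cross-checked
# against a 2e7-draw Monte Carlo during development: 1.046024 / 0.245350).
QUAD_R5 <- c(mean = 1.046063, sd = 0.245328)
QUAD_R50 <- c(mean = 1.000400, sd = 0.020032)

test_that("Monte Carlo reciprocal moments match the quadrature reference", {
  cfg <- study_config()
  mc5 <- reciprocal_stats_mc(1, 0.2, cfg)
  expect_lt(abs(mc5$mean - QUAD_R5["mean"]), 3 * mc5$se_mean)
  expect_lt(abs(mc5$sd - QUAD_R5["sd"]), 3 * mc5$se_sd)
  mc50 <- reciprocal_stats_mc(1, 0.02, cfg)
  expect_lt(abs(mc50$mean - QUAD_R50["mean"]), 3 * mc50$se_mean)
  expect_lt(abs(mc50$sd - QUAD_R50["sd"]), 3 * mc50$se_sd)
  # high-ratio limit: mean ~ 1.0004, sd ~ 0.0200 by the second-order series
  expect_equal(mc50$mean, 1.0004, tolerance = 2e-4)
  expect_equal(mc50$sd, 0.0200, tolerance = 2e-3)
})

test_that("reciprocal moments scale as 1/c under (mean, sd) -> (c mean, c sd)", {
  a <- reciprocal_stats_mc(1, 0.2, fast_config())
  b <- reciprocal_stats_mc(0.5, 0.1, fast_config())
  expect_equal(b$mean, 2 * a$mean, tolerance = 1e-12)
  expect_equal(b$sd, 2 * a$sd, tolerance = 1e-12)
})

test_that("map_z reproduces the published ratio-5 and ratio-6 equivalents", {
  cfg <- study_config()
  expect_lt(abs(map_z(2, 5, cfg)$z_y - (-1.36)), 0.08)
  expect_lt(abs(map_z(3, 5, cfg)$z_y - (-1.73)), 0.08)
  expect_lt(abs(map_z(2, 6, cfg)$z_y - (-1.48)), 0.08)
  expect_error(map_z(-6, 5, cfg), "pole")
})

test_that("map_z is deterministic per (ratio, replicate) stream", {
  a <- map_z(2, 5, fast_config())
  b <- map_z(2, 5, fast_config())
  expect_identical(a, b)
})

test_that("the mapping table has the documented shape and monotonicity", {
  cfg <- sim_config(n = 5000L, seed = 2L, replicates = 3L)
  tab <- build_mapping_table(config = cfg)
  expect_equal(dim(tab$estimate), c(10, 8))
  expect_true(all(is.finite(tab$estimate)))
  # strictly decreasing along increasing z within every ratio row
  for (i in seq_len(nrow(tab$estimate))) {
    expect_true(all(diff(tab$estimate[i, ]) < 0))
  }
  # a cell equals the stand-alone map_z call with the same config
  expect_equal(tab$estimate["ratio_5", "z_2"], map_z(2, 5, cfg)$z_y)
  # near-linear limit: the ratio-50 row approximates -z, exactly so for
  # moderate z and with a convex residual of order z^2/50 beyond
  small_z <- tab$z_values <= 1.5
  expect_lt(max(abs(tab$estimate["ratio_50", small_z] + tab$z_values[small_z])),
            0.05)
  expect_lt(max(abs(tab$estimate["ratio_50", ] + tab$z_values)), 0.4)
  expect_warning(build_mapping_table(ratios = c(55, 5), config = cfg),
                 "studied range")
})

test_that("mapping table serializes to CSV cells and JSON with provenance", {
  cfg <- sim_config(n = 2000L, seed = 3L, replicates = 2L)
  tab <- build_mapping_table(ratios = c(5, 10), z_values = c(1, 2),
                             config = cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mapping_csv(tab, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(dim(back), c(2, 3))
  expect_match(back[[2]][1], "±")
  js <- withr::local_tempfile(fileext = ".json")
  write_mapping_json(tab, js)
  prov <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(prov$config$seed, 3)
  expect_equal(prov$ratios, c(5, 10))
})

test_that("the crossing point bounds the discrepancy region and shrinks with ratio", {
  cfg <- study_config()
  roots <- vapply(c(5, 10, 20, 50),
                  function(r) crossing_point(r, cutoff(2), cfg)$z_x_star,
                  numeric(1))
  # strictly above the cut-off, decreasing in ratio, toward 2 in the limit
  expect_true(all(roots > 2))
  expect_true(all(diff(roots) < 0))
  # finite-ratio offset is ~3/ratio above the cut-off (2.065 at ratio 50)
  expect_lt(roots[4] - 2, 0.1)
  reg <- discrepancy_region(5, cutoff(2), cfg)
  expect_equal(unname(reg["lower"]), 2)
  expect_equal(unname(reg["upper"]), roots[1])
  # membership: inside the region the two scales disagree, beyond they agree
  z_in <- map_z(3, 5, cfg)$z_y
  expect_identical(classify(3, "time_per_unit")$category, "pathological")
  expect_identical(classify(z_in, "units_per_time")$category, "normal")
  z_out <- map_z(5, 5, cfg)$z_y
  expect_lt(z_out, -2)
  expect_identical(classify(z_out, "units_per_time")$category, "pathological")
})

test_that("crossing point fails loudly when the cut-off is unattainable", {
  # at ratio 5 the mapped z cannot reach -8: no sign change in the bracket
  expect_error(crossing_point(5, cutoff(8), fast_config()), "bracket")
})

test_that("normality summaries expose the reciprocal's skew", {
  x <- as.numeric(sample_normative(1, 0.2, study_config()))
  ds <- distribution_normality(x)
  expect_lt(abs(ds$skewness[ds$scale == "original"]), 0.1)
  # third central moment of the reciprocal is positive (quadrature: +0.19)
  expect_gt(ds$skewness[ds$scale == "reciprocal"], 0.5)
  expect_error(distribution_normality(x[1:10]), "at least 20")
  expect_error(distribution_normality(rep(1, 30)), "sd = 0")
})
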