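# comparison machinery and the end-to-end report pipeline

test_that("percent_deviation arithmetic and scale invariance", {
  expect_equal(percent_deviation(12, 10), 20)
  expect_equal(percent_deviation(10, 10), 0)
  expect_equal(percent_deviation(9.8, 10), 2)
  expect_error(percent_deviation(1, 0), "exp = 0")
  set.seed(1)
  for (i in 1:20) {
    sim <- stats::runif(1, 1, 50); exp <- stats::runif(1, 1, 50)
    c <- stats::runif(1, 0.1, 10)
    expect_equal(percent_deviation(c * sim, c * exp),
                 percent_deviation(sim, exp), tolerance = 1e-12)
  }
})

test_that("histogram comparison: per-bin differences and TV distance", {
  expect_equal(compare_histograms(c(3, 4), c(3, 4))$tv_distance, 0)
  expect_equal(compare_histograms(c(5, 0), c(0, 7))$tv_distance, 1)
  cmp <- compare_histograms(c(2, 2), c(1, 3))
  expect_equal(cmp$tv_distance, 0.25)
  expect_equal(unname(cmp$per_bin_diff), c(1, 1))
  expect_error(compare_histograms(c(1, 2), c(1, 2, 3)), "mismatched binning")
})

test_that("trend_similarity is a rank correlation with the expected values", {
  expect_equal(trend_similarity(1:5, 1:5), 1)
  expect_equal(trend_similarity(1:5, 5:1), -1)
  # hand-computed Spearman: d^2 = (0,1,1,1,1) -> 1 - 6*4/120 = 0.8
  expect_equal(trend_similarity(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  # invariant under strictly increasing transforms of either series
  a <- c(2, 7, 3, 9, 5); b <- c(1, 4, 2, 8, 6)
  expect_equal(trend_similarity(exp(a), b^3), trend_similarity(a, b))
  expect_error(trend_similarity(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(trend_similarity(1:2, 1:2), ">= 3")
})

test_that("analyze_condition produces the four region blocks and verdicts", {
  cu <- gen_pressure_map(cushion_scenario(seed = 31))
  ba <- gen_pressure_map(backrest_scenario(seed = 32))
  res <- analyze_condition("whole_chair_flip", 10, cushion = cu, backrest = ba,
                           cushion_split_row = 24, l1_row = 24)
  expect_setequal(names(res$region_metrics), c("hip", "legs", "waist", "back"))
  expect_setequal(names(res$comfort), c("hip", "waist"))
  expect_error(analyze_condition("whole_chair_flip", 10), "at least one")

  # a waist block whose maximum reaches 8.55 kPa exceeds the 4-8 ideal band
  ba_hot <- pressure_map(matrix(c(5, 8.55, 4, 3), 2), c(10, 10), "backrest")
  hot <- analyze_condition("backrest_flip", 25, backrest = ba_hot, l1_row = 1)
  expect_equal(hot$comfort$waist, "above_ideal")
})

test_that("error context names the failing condition and region", {
  empty_cushion <- pressure_map(matrix(0, 6, 6), c(10, 10), "cushion")
  expect_error(
    analyze_condition("whole_chair_flip", 30, cushion = empty_cushion,
                      cushion_split_row = 3),
    "whole_chair_flip 30 deg.*hip.*no contact")
})

test_that("trend_table restricts to surface metrics when internals are absent", {
  series <- gen_condition_series("whole_chair_flip", c(0, 10, 20, 30), seed = 9L)
  results <- lapply(series$conditions, function(cd)
    analyze_condition("whole_chair_flip", cd$angle, cushion = cd$cushion,
                      backrest = cd$backrest, cushion_split_row = 24,
                      l1_row = 24))  # internal dropped
  tt <- trend_table(results)
  expect_setequal(rownames(tt$similarity), colnames(tt$similarity))
  expect_null(tt$internal)

  with_int <- lapply(seq_along(results), function(i) {
    r <- results[[i]]; r$internal <- series$conditions[[i]]$internal; r
  })
  tt2 <- trend_table(with_int)
  expect_setequal(colnames(tt2$similarity),
                  c("vertebral_max_stress", "disc_max_stress", "disc_max_strain"))
  expect_true(all(abs(tt2$similarity) <= 1))
})

test_that("run_pipeline emits schema-valid, byte-reproducible reports", {
  cfg <- system.file("extdata", "study-whole-chair.yaml", package = "ergoseat")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rep1 <- run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(validate_report(file.path(d1, "report.json")))
  expect_length(rep1$conditions, 5L)
  expect_setequal(names(rep1$conditions[[1L]]$regions),
                  c("hip", "legs", "waist", "back"))
  expect_true(file.exists(file.path(d1, "metrics.csv")))
  expect_true(file.exists(file.path(d1, "trends.csv")))
})

test_that("run_pipeline reads per-condition CSV files and compares to experiment", {
  d <- withr::local_tempdir()
  angles <- c(0, 15, 30)
  conds <- lapply(angles, function(a) {
    pm <- gen_pressure_map(cushion_scenario(seed = 100 + a))
    path <- file.path(d, sprintf("cushion_%02d.csv", a))
    write_pressure_map(pm, path)
    list(angle = a, cushion_csv = path)
  })
  cfg <- list(kind = "whole_chair_flip", conditions = conds,
              cell_pitch = c(12.7, 12.7), cushion_split_row = 24,
              experimental = list(hip.p_max = 10))
  rep <- run_pipeline(cfg)
  expect_length(rep$conditions, 3L)
  cmp <- rep$comparison[[1L]]
  expect_equal(cmp$percent_deviation,
               100 * abs(cmp$simulated - 10) / 10)
  # missing file fails fast with condition context
  cfg$conditions[[2L]]$cushion_csv <- file.path(d, "nope.csv")
  expect_error(run_pipeline(cfg), "missing file.*angle 15")
})
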