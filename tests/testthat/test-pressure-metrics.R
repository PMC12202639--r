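# surface-comfort statistics against hand values and an independent
# brute-force oracle

test_that("contact_cells applies a strict threshold", {
  pm <- pressure_map(matrix(c(0, 2, 1, 3), 2), c(10, 10), "cushion")
  expect_equal(nrow(contact_cells(pm)), 3L)
  expect_equal(nrow(contact_cells(pm, threshold = 2)), 1L)
  z <- pressure_map(matrix(0, 3, 3), c(10, 10), "cushion")
  expect_equal(nrow(contact_cells(z)), 0L)
})

test_that("compute_spd matches hand-evaluated values and is scale invariant", {
  pm <- pressure_map(matrix(c(1, 3), 1), c(10, 10), "cushion")
  expect_equal(compute_spd(pm), 0.0625)          # pave=2, sum=2, denom=32
  pm2 <- pressure_map(matrix(c(2, 6), 1), c(10, 10), "cushion")
  expect_equal(compute_spd(pm2), 0.0625)         # SPD(c*p) = SPD(p)
  u <- pressure_map(matrix(5, 4, 4), c(10, 10), "cushion")
  expect_equal(compute_spd(u), 0)
  z <- pressure_map(matrix(0, 2, 2), c(10, 10), "cushion")
  expect_error(compute_spd(z), "no contact")
})

test_that("SPD properties hold on 100 random maps", {
  for (s in 1:100) {
    pm <- random_map(s)
    spd <- compute_spd(pm)
    expect_gte(spd, 0)
    # scale invariance to 1e-12
    pm_scaled <- pressure_map(pm$grid * 3.7, pm$cell_pitch, pm$interface)
    expect_equal(compute_spd(pm_scaled), spd, tolerance = 1e-12)
    # SPD = 0 iff all contact pressures equal
    vals <- pm$grid[pm$grid > 0]
    expect_identical(spd < 1e-12, max(vals) - min(vals) < 1e-12)
    # appending a cell at p_ave decreases SPD (sum unchanged, n grows)
    if (spd > 0) {
      g2 <- cbind(pm$grid, c(mean(vals), rep(0, nrow(pm$grid) - 1L)))
      expect_lt(compute_spd(pressure_map(g2, pm$cell_pitch, pm$interface)), spd)
    }
  }
})

test_that("compute_metrics equals the brute-force oracle on 100 random maps", {
  pm <- pressure_map(matrix(c(0, 2, 1, 3), 2), c(10, 10), "cushion")
  m <- compute_metrics(pm)
  expect_equal(m$p_max, 3); expect_equal(m$p_ave, 2); expect_equal(m$n_contact, 3L)

  one <- pressure_map(matrix(c(10, 0, 0, 0), 2), c(10, 10), "cushion")
  m1 <- compute_metrics(one)
  expect_equal(m1$p_max, 10); expect_equal(m1$p_ave, 10)
  expect_equal(m1$contact_area, 1); expect_equal(m1$spd, 0)

  for (s in 1:100) {
    pm <- random_map(s + 500)
    ref <- brute_metrics(pm)
    m <- compute_metrics(pm)
    expect_equal(m$p_max, ref$p_max)
    expect_equal(m$p_ave, ref$p_ave)
    expect_equal(m$n_contact, ref$n)
    expect_equal(m$contact_area, ref$area_cm2)
    expect_equal(m$spd, ref$spd, tolerance = 1e-12)
    expect_equal(m$one_minus_spd, 1 - m$spd)
  }
})

test_that("bin_histogram uses half-open bins and counts sum to n_contact", {
  pm <- pressure_map(matrix(c(1, 5, 9, 0), 2), c(10, 10), "cushion")
  h <- bin_histogram(pm, bin_width = 4)
  expect_equal(unname(h), c(1L, 1L, 1L))
  # value exactly on a bin edge falls in the upper bin
  pm4 <- pressure_map(matrix(4, 1, 1), c(10, 10), "cushion")
  expect_equal(unname(bin_histogram(pm4, bin_width = 4)), c(0L, 1L))
  # empty region -> all-zero histogram
  z <- pressure_map(matrix(0, 2, 2), c(10, 10), "cushion")
  expect_equal(sum(bin_histogram(z)), 0L)
  for (s in 1:50) {
    pm <- random_map(s + 900)
    h <- bin_histogram(pm, bin_width = 2.5, threshold = 1)
    expect_equal(sum(h), nrow(contact_cells(pm, threshold = 1)))
    expect_equal(unname(h), brute_metrics(pm, threshold = 1, bin_width = 2.5)$hist)
  }
})

test_that("backrest and cushion partitions are disjoint and exhaustive", {
  bm <- pressure_map(matrix(1, 10, 4), c(10, 10), "backrest")
  p <- partition_backrest(bm, l1_row = 5)
  expect_setequal(names(p), c("waist", "back"))
  expect_equal(sort(unique(p$back$cells[, "row"])), 1:5)    # rows above the line
  expect_equal(sort(unique(p$waist$cells[, "row"])), 6:10)  # rows below, toward cushion

  cm <- pressure_map(matrix(1, 20, 3), c(10, 10), "cushion")
  for (r in 1:20) {
    # r = 20 leaves 'legs' empty, which warns; the warning itself is
    # asserted below
    p <- suppressWarnings(partition_cushion(cm, split_row = r))
    cells <- rbind(p$hip$cells, p$legs$cells)
    expect_equal(nrow(cells), 60L)                           # exhaustive
    expect_false(anyDuplicated(cells) > 0)                   # disjoint
  }
  expect_warning(partition_cushion(cm, split_row = 20), "empty")
  expect_error(partition_cushion(cm, split_row = 25), "outside")
  expect_error(partition_backrest(cm, 3), "interface")
})

test_that("comfort classification against the ideal ranges", {
  expect_equal(classify_comfort(9, "hip"), "within_ideal")
  expect_equal(classify_comfort(8.55, "waist"), "above_ideal")
  expect_equal(classify_comfort(4.0, "waist"), "within_ideal")  # closed bound
  expect_equal(classify_comfort(11, "hip"), "within_ideal")     # closed bound
  expect_equal(classify_comfort(6.9, "hip"), "below_ideal")
  expect_error(classify_comfort(5, "legs"), "no ideal range")
})
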