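test_that("calibration offset is a plain additive correction", {
  p <- calibration_profile(c_offset = 0, b_min = 0, b_max = 500)
  expect_equal(apply_offset(300, p), 300)
  p2 <- calibration_profile(c_offset = -25, b_min = 0, b_max = 500)
  expect_equal(apply_offset(300, p2), 275)
  expect_equal(apply_offset(0, calibration_profile(10, 0, 500)), 10)
  expect_error(apply_offset(NaN, p), "finite")
})

test_that("profiles with a degenerate baseline range are rejected", {
  expect_error(calibration_profile(b_min = 100, b_max = 100), "strictly greater")
  expect_error(calibration_profile(b_min = 100, b_max = 50), "strictly greater")
})

test_that("normalization anchors, midpoint, and monotonicity", {
  p <- calibration_profile(b_min = 100, b_max = 300)
  expect_equal(normalize_gsr(300, p)$gsr_norm, 500)
  expect_equal(normalize_gsr(100, p)$gsr_norm, 0)
  expect_equal(normalize_gsr(200, p)$gsr_norm, 250)
  x <- seq(100, 300, by = 0.5)
  expect_true(all(diff(normalize_gsr(x, p)$gsr_norm) > 0))
})

test_that("normalization anchors hold for random valid profiles", {
  set.seed(5)
  for (i in 1:200) {
    b_min <- runif(1, -100, 900)
    b_max <- b_min + runif(1, 1e-3, 800)
    p <- calibration_profile(runif(1, -50, 50), b_min, b_max)
    expect_equal(normalize_gsr(b_min, p)$gsr_norm, 0, tolerance = 1e-9)
    expect_equal(normalize_gsr(b_max, p)$gsr_norm, 500, tolerance = 1e-9)
  }
})

test_that("out-of-range readings are clamped and flagged", {
  p <- calibration_profile(b_min = 100, b_max = 300)
  out <- normalize_gsr(c(50, 100, 200, 300, 350), p)
  expect_equal(out$gsr_norm, c(0, 0, 250, 500, 500))
  expect_equal(out$clamped, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("classification reproduces printed cohort readings and boundaries", {
  expect_equal(as.character(classify_stress(432)), "Very high stress")
  expect_equal(as.character(classify_stress(c(378, 254, 189))),
               c("High stress", "Minor stress", "No stress"))
  # band edges are upper-inclusive
  expect_equal(as.character(classify_stress(c(200, 300, 400))),
               c("No stress", "Minor stress", "High stress"))
  expect_equal(as.character(classify_stress(c(200.0001, 400.0001))),
               c("Minor stress", "Very high stress"))
  # values above 500 remain classifiable (printed tables contain 501)
  expect_equal(as.character(classify_stress(501)), "Very high stress")
  expect_error(classify_stress(-1), "non-negative")
})

test_that("every value on a fine grid gets exactly one band, monotonically", {
  grid <- seq(0, 500, by = 0.01)
  lev <- classify_stress(grid)
  expect_false(anyNA(lev))
  expect_true(!is.unsorted(lev))
  expect_equal(sum(lev == "No stress"), sum(grid <= 200))
  expect_equal(sum(lev == "Minor stress"), sum(grid > 200 & grid <= 300))
  expect_equal(sum(lev == "High stress"), sum(grid > 300 & grid <= 400))
  expect_equal(sum(lev == "Very high stress"), sum(grid > 400))
})

test_that("baseline estimation is min/max over the window with guards", {
  w <- c(100, 150, 120, 110, 130, 140, 125, 115, 135, 145)
  p <- estimate_baseline(w)
  expect_equal(p$b_min, 100)
  expect_equal(p$b_max, 150)
  # upward guard fraction widens only the top
  p2 <- estimate_baseline(w, eps = 0.1)
  expect_equal(p2$b_max, 150 + 0.1 * 50)
  expect_equal(p2$b_min, 100)
  # a single outlier is kept: no rejection by default
  p3 <- estimate_baseline(c(w[-1], 900))
  expect_equal(p3$b_max, 900)
  expect_error(estimate_baseline(w[1:5]), "insufficient calibration")
  expect_error(estimate_baseline(rep(7, 12)), "degenerate baseline")
})

test_that("per-subject band counts cover the bundled cohort table", {
  tab <- load_table2_fixture()
  counts <- classify_table(tab)
  expect_equal(rownames(counts), stress_levels())
  expect_equal(counts[["Person 1"]], c(0L, 0L, 0L, 14L))
  expect_equal(counts[["Person 4"]], c(14L, 0L, 0L, 0L))
  # every column is pure in its header band
  band <- attr(tab, "band")
  for (cn in names(tab)) {
    n_col <- sum(!is.na(tab[[cn]]))
    expect_equal(counts[[cn]][match(as.character(band[[cn]]), stress_levels())],
                 n_col, info = cn)
    expect_equal(sum(counts[[cn]]), n_col, info = cn)
  }
})

test_that("band counts reject non-numeric cells with row/column coordinates", {
  bad <- data.frame(`Person 1` = c("100", "oops"), check.names = FALSE)
  expect_error(classify_table(bad), "row 2, column \"Person 1\"")
  empty <- data.frame(`Person 1` = numeric(), check.names = FALSE)
  expect_equal(classify_table(empty)[["Person 1"]], rep(0L, 4))
})
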