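# brute-force order-statistics oracle for the boxplot summary
oracle_boxplot <- function(v) {
  v <- sort(v)
  n <- length(v)
  qat <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  q1 <- qat(0.25); md <- qat(0.5); q3 <- qat(0.75)
  iqr <- q3 - q1
  inside <- v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
  list(q1 = q1, median = md, q3 = q3, iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       notch_low = md - 1.57 * iqr / sqrt(n),
       notch_high = md + 1.57 * iqr / sqrt(n),
       outliers = sort(v[v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr]))
}

test_that("the hand-computable example matches the notch formula", {
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$notch_low, 3 - 1.57 * 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(b$notch_high, 3 + 1.57 * 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(round(c(b$notch_low, b$notch_high), 3), c(1.596, 4.404))
})

test_that("degenerate lists are handled", {
  b1 <- boxplot_stats(7)
  expect_equal(b1$median, 7)
  expect_equal(b1$iqr, 0)
  expect_equal(b1$notch_low, b1$notch_high)
  expect_length(b1$outliers, 0)
  bc <- boxplot_stats(rep(2, 9))
  expect_length(bc$outliers, 0)
  expect_equal(bc$whisker_low, 2)
  expect_equal(bc$whisker_high, 2)
  expect_error(boxplot_stats(numeric(0)), "empty")
})

test_that("boxplot_stats agrees exactly with a brute-force oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:20, 1)
    v <- round(rnorm(n, 10, 4), 3)
    b <- boxplot_stats(v)
    o <- oracle_boxplot(v)
    for (f in names(o))
      expect_equal(b[[f]], o[[f]], tolerance = 1e-12,
                   info = paste("field", f, "iter", i))
  }
})

test_that("notch width scales as 1/sqrt(n)", {
  # length-5 list: quartile positions land on order statistics for both n
  # and 2n, so median and IQR are invariant under doubling
  v <- c(2.2, 3.1, 4.8, 6.7, 7.9)
  b1 <- boxplot_stats(v)
  b2 <- boxplot_stats(c(v, v))
  expect_equal(b2$median, b1$median)
  expect_equal(b2$iqr, b1$iqr)
  hw1 <- (b1$notch_high - b1$notch_low) / 2
  hw2 <- (b2$notch_high - b2$notch_low) / 2
  expect_equal(hw2, hw1 / sqrt(2), tolerance = 1e-12)
})

test_that("summaries report mean, sd, range and n in the reporting style", {
  s <- summarize_values(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$min, 2)
  expect_equal(s$max, 4)
  expect_equal(s$n, 2L)
  expect_equal(summarize_values(c(5, 5, 5))$sd, 0)
  expect_match(summarize_values(rnorm(30, 5, 1.5))$report,
               "^[0-9.]+±[0-9.]+ nm \\(range [0-9.]+–[0-9.]+ nm, n = 30\\)$")
})

test_that("notch overlap decides significance", {
  a <- c(1, 2, 3, 4, 5)
  cmp_same <- notch_overlap_test(a, a)
  expect_identical(cmp_same$verdict, "not_significant")
  expect_true(cmp_same$notch_overlap)
  cmp_far <- notch_overlap_test(a, a + 100)
  expect_identical(cmp_far$verdict, "significant")
  expect_false(cmp_far$notch_overlap)
})

test_that("group draws from the two contrast populations separate as expected", {
  sig <- notsig <- 0
  for (s in 1:20) {
    set.seed(s)
    gap_wt <- rnorm(60, 5.2, 2.0)
    gap_mut <- rnorm(60, 8.9, 3.8)
    if (notch_overlap_test(gap_wt, gap_mut)$verdict == "significant")
      sig <- sig + 1
    d_wt <- rnorm(60, 4.5, 0.9)
    d_mut <- rnorm(60, 4.6, 0.8)
    if (notch_overlap_test(d_wt, d_mut)$verdict == "not_significant")
      notsig <- notsig + 1
  }
  expect_gte(sig, 18)
  expect_gte(notsig, 18)
})

test_that("the comparison figure renders from computed statistics", {
  cmp <- notch_overlap_test(rnorm(40, 5, 1), rnorm(40, 8, 2),
                            labels = c("WT", "Mutant"))
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_silent(plot(cmp, ylab = "edge gap (nm)"))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("threshold sensitivity reproduces the base run at delta zero", {
  spec <- make_preset("cryo", shape_voxels = c(64L, 80L, 36L), seed = 3)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  cfg <- wall_config(polarity = "dense_dark")
  tab <- threshold_sensitivity(img, analysis_roi(group = "cryo"), cfg,
                               deltas = c(-0.05, 0, 0.05))
  expect_equal(tab$diameter_shift_nm[tab$delta == 0], 0)
  base <- analyze_roi(img, analysis_roi(group = "cryo"), cfg)
  expect_equal(tab$mean_diameter_nm[tab$delta == 0],
               mean(base$value_nm[base$type == "diameter"]))
  expect_error(threshold_sensitivity(img, analysis_roi(), cfg,
                                     deltas = c(-0.1, 0.1)), "include 0")
})
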