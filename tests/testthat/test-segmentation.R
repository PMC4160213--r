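test_that("normalize_density standardizes, is idempotent, and handles polarity", {
  set.seed(1)
  arr <- array(rnorm(10 * 10 * 10, 5, 2), c(10, 10, 10))
  v <- density_volume(arr, 1)
  n1 <- normalize_density(v)
  expect_lt(abs(mean(n1$data)), 1e-9)
  expect_lt(abs(sd(n1$data) - 1), 1e-9)
  n2 <- normalize_density(n1)
  expect_lt(max(abs(n2$data - n1$data)), 1e-9)
  nd <- normalize_density(v, "dense_dark")
  expect_lt(max(abs(nd$data + n1$data)), 1e-9)
  expect_error(normalize_density(density_volume(array(1, c(8, 8, 8)), 1)),
               "no contrast")
})

test_that("z-scoring maps a bright minority class to positive values", {
  arr <- array(0, c(10, 10, 10))
  arr[sample(length(arr), 100)] <- 4     # 10% high voxels
  v <- normalize_density(density_volume(arr, 1))
  expect_true(all(v$data[arr == 4] > 0))
})

test_that("threshold segmentation saturates at the extremes", {
  set.seed(2)
  v <- normalize_density(density_volume(array(rnorm(1000), c(10, 10, 10)), 1))
  lab_all <- threshold_segment(v, min(v$data) - 1)
  expect_equal(lab_all$n_components, 1L)
  expect_true(all(lab_all$labels > 0))
  lab_none <- threshold_segment(v, max(v$data) + 1)
  expect_equal(lab_none$n_components, 0L)
})

test_that("a noiseless two-cylinder phantom segments exactly at the mid level", {
  fib <- data.frame(z = c(10, 10), y = c(24, 24), x = c(8, 18),
                    uz = 0, uy = 1, ux = 0, radius_nm = 2.5)
  mp <- manual_phantom(fib, shape_voxels = c(28L, 56L, 24L), voxel_size = 1)
  nv <- normalize_density(mp$volume)
  # the raw mid level 0.5 maps through the same affine standardization
  thr <- (0.5 - mean(mp$volume$data)) / sd(mp$volume$data)
  lab <- threshold_segment(nv, thr)
  expect_identical(lab$labels > 0, mp$volume$data > 0.5)
  expect_equal(lab$n_components, 2L)
})

test_that("contour spectrum volume fraction is monotone and steps at levels", {
  arr <- array(0, c(12, 12, 12))
  arr[sample(length(arr), round(0.1 * length(arr)))] <- 1
  v <- density_volume(arr + rnorm(length(arr), 0, 1e-4), 1)
  cs <- contour_spectrum(v, 16)
  expect_true(all(diff(cs$volume_fraction) <= 1e-12))
  expect_gt(cs$volume_fraction[1], 0.95)
  mid <- which.min(abs(cs$isovalue - 0.5))
  expect_lt(abs(cs$volume_fraction[mid] - 0.10), 0.02)
})

test_that("isosurface area peaks strictly between the levels of a sphere", {
  d <- c(40L, 40L, 40L)
  arr <- wallfibril3d:::cpp_add_capsules(
    as.numeric(array(0, d)), as.integer(d),
    matrix(c(19.5, 19.5, 19.5, 19.5, 19.5, 19.5, 9, 1), 1), 1.0)
  dim(arr) <- d
  set.seed(8)
  arr <- arr + array(rnorm(length(arr), 0, 0.02), d)
  cs <- contour_spectrum(density_volume(arr, 1), 16)
  k <- which.max(cs$area)
  expect_gt(k, 1)
  expect_lt(k, nrow(cs))
})

test_that("select_isovalue lands between the two levels of a step volume", {
  set.seed(11)
  arr <- array(0, c(16, 16, 16))
  arr[, , 9:16] <- 1
  arr <- arr + array(rnorm(length(arr), 0, 0.01), dim(arr))
  cs <- contour_spectrum(density_volume(arr, 1), 16)
  iso <- select_isovalue(cs)
  frac <- cs$volume_fraction[which.min(abs(cs$isovalue - iso))]
  expect_lt(abs(frac - 0.5), 0.05)   # the selected level cuts the interface
  expect_lt(iso, 0.95)
})

test_that("select_isovalue warns and returns the median on flat spectra", {
  cs <- structure(data.frame(isovalue = 1:10, volume_fraction = seq(1, 0.1, -0.1),
                             area = rep(1, 10), mean_gradient = rep(2, 10)),
                  class = c("contour_spectrum", "data.frame"))
  expect_warning(iso <- select_isovalue(cs), "flat")
  expect_equal(iso, 5.5)
})

test_that("isovalue selection is invariant to affine intensity rescaling", {
  set.seed(5)
  mp <- cylinder_fixture(r_nm = 3, vs = 1, ny = 40, nzx = 24)
  raw <- mp$volume$data + array(rnorm(length(mp$volume$data), 0, 0.05),
                                dim(mp$volume$data))
  pick <- function(x) {
    nv <- normalize_density(density_volume(x, 1))
    select_isovalue(contour_spectrum(nv, 16))
  }
  expect_equal(pick(raw), pick(raw * 7 + 3), tolerance = 1e-9)
})

test_that("clean_components removes specks and relabels contiguously", {
  arr <- array(FALSE, c(12, 40, 12))
  arr[5:7, 5:36, 5:7] <- TRUE                 # ~300-voxel rod
  specks <- rbind(c(2, 2, 2), c(10, 38, 2), c(2, 38, 10), c(10, 2, 10),
                  c(1, 20, 1))
  for (k in seq_len(nrow(specks)))
    arr[specks[k, 1] + 0:1, specks[k, 2], specks[k, 3]] <- TRUE
  lab <- threshold_segment(density_volume(arr + 0, 1), 0.5)
  expect_equal(lab$n_components, 6L)
  cleaned <- clean_components(lab, 8L)
  expect_equal(cleaned$n_components, 1L)
  expect_equal(attr(cleaned, "removed"), 5L)
  expect_identical(sort(unique(as.vector(cleaned$labels))), c(0L, 1L))
  # identity and empty-mask behavior
  expect_equal(clean_components(lab, 1L)$n_components, 6L)
  empty <- threshold_segment(density_volume(array(0, c(8, 8, 8)) -
                                              seq(0, 1, length.out = 512),
                                            1), 2)
  expect_equal(clean_components(empty, 5L)$n_components, 0L)
})

test_that("hysteresis keeps faint material only when seeded", {
  arr <- array(0, c(12, 30, 12))
  arr[5:7, 3:27, 5:7] <- 0.4        # faint rod
  arr[5:7, 3:8, 5:7] <- 1.0         # bright seed on one end
  arr[9:10, 3:5, 9:10] <- 0.4       # isolated faint blob
  v <- density_volume(arr, 1)
  lab <- hysteresis_segment(v, 0.2, 0.8)
  expect_true(all(lab$labels[5:7, 3:27, 5:7] > 0))
  expect_true(all(lab$labels[9:10, 3:5, 9:10] == 0))
})
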