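test_that("the structure tensor vanishes on a constant volume", {
  v <- density_volume(array(5, c(10, 12, 14)), 1)
  tf <- compute_structure_tensor(v, 1, 2)
  expect_lt(max(abs(tf$lambda)), 1e-12)
})

test_that("the minor eigenvector tracks a cylinder axis", {
  cf <- cylinder_fixture(r_nm = 3, vs = 1, ny = 40, nzx = 24)
  tf <- compute_structure_tensor(cf$volume, 1, 3)
  d <- dim(cf$volume$data)
  lin <- function(z, y, x) z + 1 + d[1] * (y + d[2] * x)
  onax <- vapply(10:30, function(y) abs(tf$v3[lin(11, y, 11), 2]), numeric(1))
  expect_gte(median(onax), 0.99)
})

test_that("the major eigenvector is normal to a planar interface", {
  arr <- array(0, c(24, 24, 24))
  arr[, , 13:24] <- 1                      # step with normal along x
  v <- density_volume(arr, 1)
  tf <- compute_structure_tensor(v, 1, 2)
  d <- dim(arr)
  lin <- function(z, y, x) z + 1 + d[1] * (y + d[2] * x)
  near <- vapply(6:18, function(z) abs(tf$v1[lin(z, 12, 12), 3]), numeric(1))
  expect_gte(median(near), 0.99)
})

test_that("NAD leaves constant volumes untouched and conserves mass", {
  cv <- density_volume(array(3, c(10, 10, 10)), 1)
  out <- nad_filter(cv, diffusion_params(iterations = 3, voxel_size_nm = 1))
  expect_equal(out$data, cv$data)
  set.seed(1)
  arr <- array(rnorm(20 * 22 * 24), c(20, 22, 24)) + 2
  v <- density_volume(arr, 1)
  f <- nad_filter(v, diffusion_params(iterations = 5, voxel_size_nm = 1))
  expect_lt(abs(sum(f$data) - sum(arr)) / abs(sum(arr)), 1e-6)
})

test_that("NAD reduces background noise variance", {
  set.seed(2)
  arr <- array(rnorm(24 * 48 * 48, 0, 0.3), c(24, 48, 48))
  arr[10:14, , ] <- arr[10:14, , ] + 1
  v <- density_volume(arr, 1)
  f <- nad_filter(v, diffusion_params(iterations = 10, voxel_size_nm = 1))
  expect_lt(var(as.vector(f$data[1:6, , ])), var(as.vector(arr[1:6, , ])))
})

test_that("diffusion parameters are validated", {
  expect_error(diffusion_params(time_step = 0.2), "0.15")
  expect_error(diffusion_params(iterations = 0), "iterations")
  expect_error(diffusion_params(K = -1), "K")
})

test_that("orientation smoothing matches isotropic Gaussian in the isotropic limit", {
  set.seed(3)
  arr <- array(rnorm(20 * 20 * 20), c(20, 20, 20))
  v <- density_volume(arr, 1)
  tf <- compute_structure_tensor(v, 1, 2)
  a <- orientation_smooth(v, tf, 1.5, 1.5)
  g <- wallfibril3d:::cpp_gauss3d(as.numeric(arr), as.integer(dim(arr)),
                                  rep(1.5, 3))
  dim(g) <- dim(arr)
  core <- 7:14
  expect_lt(max(abs(a$data[core, core, core] - g[core, core, core])), 1e-6)
})

test_that("orientation smoothing preserves constants and checks shapes", {
  cv <- density_volume(array(2, c(12, 12, 12)), 1)
  tf <- compute_structure_tensor(cv, 1, 2)
  out <- orientation_smooth(cv, tf, 2, 0.5)
  expect_lt(max(abs(out$data - 2)), 1e-6)
  other <- density_volume(array(0, c(10, 10, 10)), 1)
  expect_error(orientation_smooth(other, tf, 2, 0.5), "shape")
})

test_that("orientation smoothing beats isotropic smoothing on a noisy cylinder", {
  set.seed(4)
  cf <- cylinder_fixture(r_nm = 2.5, vs = 1, ny = 48, nzx = 20)
  noise <- array(rnorm(length(cf$volume$data), 0, 0.5), dim(cf$volume$data))
  noisy <- density_volume(cf$volume$data + noise, 1)
  tf <- compute_structure_tensor(cylinder_fixture(r_nm = 2.5, vs = 1,
                                                  ny = 48, nzx = 20)$volume,
                                 1, 3)
  an <- orientation_smooth(noisy, tf, 3, 0.8)
  g <- wallfibril3d:::cpp_gauss3d(as.numeric(noisy$data),
                                  as.integer(dim(noisy$data)), rep(0.8, 3))
  dim(g) <- dim(noisy$data)
  d <- dim(g)
  onax <- cbind(10, 12:36, 10)
  bg <- as.vector(noisy$data[1:4, , 1:4])
  cnr <- function(a) {
    sig <- mean(a[onax[, 1] + 1 + d[1] * (onax[, 2] + d[2] * onax[, 3])])
    sig / sd(as.vector(a[1:4, , 1:4]))
  }
  expect_gt(cnr(an$data), cnr(g))
})

test_that("the minor eigenvector recovers true fibril axes on a phantom", {
  spec <- make_preset("cryo", shape_voxels = c(72L, 96L, 40L), seed = 7,
                      snr = Inf, psf_sigma = 0,
                      missing_wedge_halfangle_deg = 90)
  ph <- generate_wall_phantom(spec)
  tf <- compute_structure_tensor(ph$volume)
  d <- dim(ph$volume$data)
  fb <- ph$truth$fibrils
  aligns <- numeric(0)
  for (i in seq_len(nrow(fb))) {
    u <- c(fb$uz[i], fb$uy[i], fb$ux[i])
    for (ynm in seq(10, 70, by = 10)) {
      p <- round(c(fb$z[i] + (ynm - fb$y[i]) * fb$uz[i] / fb$uy[i],
                   ynm,
                   fb$x[i] + (ynm - fb$y[i]) * fb$ux[i] / fb$uy[i]) / 0.87)
      if (any(p < 1) || any(p >= d - 1)) next
      v3 <- tf$v3[p[1] + 1 + d[1] * (p[2] + d[2] * p[3]), ]
      aligns <- c(aligns, abs(sum(v3 * u)))
    }
  }
  expect_gte(median(aligns), 0.95)
})
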