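test_that("presets carry the measured condition parameters", {
  expect_equal(make_preset("cryo")$fibril_diameter_mean, 5.0)
  expect_equal(make_preset("cryo")$fibril_diameter_sd, 1.5)
  expect_equal(make_preset("cryo")$edge_gap_mean, 6.4)
  expect_identical(make_preset("cryo")$contrast_mode, "cryo")
  expect_equal(make_preset("extracted")$crosslink_density, 0)
  expect_equal(make_preset("extracted")$fibril_diameter_mean, 4.3)
  expect_equal(make_preset("cob6")$edge_gap_mean, 8.9)
  expect_equal(make_preset("hpf")$crosslink_length_mean, 4.6)
  expect_equal(make_preset("wt_hypocotyl")$edge_gap_sd, 2.0)
  expect_equal(make_preset("chem")$voxel_size, 0.87)
  expect_identical(make_preset("chem")$shape_voxels, c(500L, 500L, 75L))
  expect_error(make_preset("nope"), "unknown preset")
})

small_spec <- function(seed = 7, ...) {
  make_preset("cryo", shape_voxels = c(72L, 96L, 40L), seed = seed, ...)
}

test_that("generation is deterministic for a fixed seed", {
  a <- generate_wall_phantom(small_spec())
  b <- generate_wall_phantom(small_spec())
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$fibrils, b$truth$fibrils)
  expect_identical(a$truth$crosslinks, b$truth$crosslinks)
})

test_that("ground truth pair identity holds exactly", {
  ph <- generate_wall_phantom(small_spec())
  tp <- ph$truth$true_pair_table
  r <- ph$truth$fibrils$radius_nm
  expect_gt(nrow(tp), 0)
  expect_lt(max(abs(tp$center_nm - (tp$edge_nm + r[tp$i] + r[tp$j]))), 1e-6)
})

test_that("a two-cylinder layout yields the analytic pair row", {
  fib <- data.frame(z = c(10, 10), y = c(20, 20), x = c(10, 20),
                    uz = 0, uy = 1, ux = 0, radius_nm = 2.5)
  mp <- manual_phantom(fib, shape_voxels = c(40L, 48L, 40L), voxel_size = 1)
  tp <- mp$truth$true_pair_table
  expect_equal(tp$center_nm, 10, tolerance = 1e-6)
  expect_equal(tp$edge_nm, 5, tolerance = 1e-6)
})

test_that("cross-link endpoints lie on their fibril surfaces", {
  ph <- generate_wall_phantom(small_spec(seed = 3))
  cl <- ph$truth$crosslinks
  expect_gt(nrow(cl), 0)
  fb <- ph$truth$fibrils
  for (k in seq_len(nrow(cl))) {
    for (side in c("a", "b")) {
      fid <- if (side == "a") cl$fibril_i[k] else cl$fibril_j[k]
      p <- if (side == "a") c(cl$az[k], cl$ay[k], cl$ax[k]) else
        c(cl$bz[k], cl$by[k], cl$bx[k])
      c0 <- c(fb$z[fid], fb$y[fid], fb$x[fid])
      u <- c(fb$uz[fid], fb$uy[fid], fb$ux[fid])
      w <- p - c0
      dist_axis <- sqrt(sum((w - sum(w * u) * u)^2))
      expect_lt(abs(dist_axis - fb$radius_nm[fid]), 0.25 * 0.87)
    }
  }
})

test_that("generated samples match the preset moments within 3 SE", {
  dmv <- gmv <- cmv <- numeric(0)
  for (s in 1:4) {
    ph <- generate_wall_phantom(small_spec(seed = s,
                                           shape_voxels = c(120L, 120L, 44L)))
    tp <- ph$truth$true_pair_table
    dmv <- c(dmv, 2 * ph$truth$fibrils$radius_nm)
    gmv <- c(gmv, tp$gap_mid_nm[tp$type == "within_layer"])
    cmv <- c(cmv, ph$truth$crosslinks$length_nm)
  }
  expect_lt(abs(mean(dmv) - 5.0), 3 * 1.5 / sqrt(length(dmv)) + 0.1)
  expect_lt(abs(mean(gmv) - 6.4), 3 * 1.2 / sqrt(length(gmv)) + 0.1)
  expect_lt(abs(mean(cmv) - 5.0), 3 * 1.5 / sqrt(length(cmv)) + 0.25)
})

test_that("zero cross-link density yields an empty cross-link set", {
  spec <- make_preset("extracted", shape_voxels = c(72L, 80L, 40L), seed = 5)
  ph <- generate_wall_phantom(spec)
  expect_equal(nrow(ph$truth$crosslinks), 0)
})

test_that("the imaging model is the identity when disabled", {
  spec <- make_preset("hpf", shape_voxels = c(48L, 64L, 32L), seed = 2,
                      snr = Inf, psf_sigma = 0,
                      missing_wedge_halfangle_deg = 90,
                      artifact_blob_rate = 0)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  expect_identical(img$data, ph$volume$data)
})

test_that("noise on a featureless volume has sd contrast/snr", {
  spec <- phantom_spec(shape_voxels = c(48L, 48L, 48L), snr = 3,
                       psf_sigma = 0, missing_wedge_halfangle_deg = 90,
                       artifact_blob_rate = 0, seed = 9)
  flat <- density_volume(array(0, c(48, 48, 48)), spec$voxel_size)
  img <- apply_imaging_model(flat, spec)
  expect_lt(abs(stats::sd(img$data) - 1 / 3) / (1 / 3), 0.05)
})

test_that("the missing wedge elongates a sphere along the beam axis", {
  d <- c(48L, 48L, 48L)
  arr <- wallfibril3d:::cpp_add_capsules(
    as.numeric(array(0, d)), as.integer(d),
    matrix(c(23.5, 23.5, 23.5, 23.5, 23.5, 23.5, 5, 1), 1), 1.0)
  dim(arr) <- d
  out <- wallfibril3d:::apply_missing_wedge(arr, 60, "single", 0)
  hw <- function(prof) {
    pk <- max(prof)
    sum(prof > pk / 2)
  }
  axial <- hw(out[, 24, 24])     # along z
  lateral <- hw(out[24, 24, ])   # along x (perpendicular to tilt axis)
  expect_gt(axial / lateral, 1)
})

test_that("non-finite volumes are rejected", {
  spec <- small_spec()
  bad <- density_volume(array(1, c(16, 16, 16)), 0.87)
  bad$data[1] <- NA
  expect_error(apply_imaging_model(bad, spec), "finite")
})

test_that("ground truth tables are written as plain text", {
  ph <- generate_wall_phantom(small_spec())
  dir <- withr::local_tempdir()
  write_ground_truth(ph$truth, dir)
  expect_true(all(file.exists(file.path(dir, c("fibrils.csv",
                                               "crosslinks.csv", "pairs.csv",
                                               "spec.json")))))
  fib <- read.csv(file.path(dir, "fibrils.csv"))
  expect_equal(nrow(fib), nrow(ph$truth$fibrils))
})
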