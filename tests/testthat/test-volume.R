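test_that("MRC volumes round-trip with voxel size in Angstrom", {
  arr <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  vol <- density_volume(arr, 0.87)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$voxel_size, 0.87, tolerance = 1e-6)
  expect_lt(max(abs(back$data - arr)), 1e-6)
})

test_that("TIFF stacks round-trip but need an explicit voxel size", {
  arr <- array(runif(5 * 6 * 7), c(5, 6, 7))
  vol <- density_volume(arr, 1.1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)
  expect_error(read_volume(path), "voxel size")
  back <- read_volume(path, voxel_size = 1.1)
  expect_lt(max(abs(back$data - arr)), 1e-6)
})

test_that("unreadable inputs give clean errors", {
  expect_error(read_volume("absent.mrc"), "not found")
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), path)
  expect_error(read_volume(path), "truncated")
  path2 <- withr::local_tempfile(fileext = ".xyz")
  writeBin(raw(10), path2)
  expect_error(read_volume(path2), "supported")
})

test_that("binning averages blocks and scales the voxel size", {
  arr <- array(seq_len(8 * 8 * 8), c(8, 8, 8))
  vol <- density_volume(arr, 0.435)
  b <- bin_volume(vol, 2L)
  expect_equal(dim(b$data), c(4L, 4L, 4L))
  expect_equal(b$voxel_size, 0.87, tolerance = 1e-9)
  expect_equal(b$data[1, 1, 1], mean(arr[1:2, 1:2, 1:2]))
  expect_identical(bin_volume(vol, 1L), vol)
  cv <- density_volume(array(3, c(8, 8, 8)), 1)
  expect_true(all(bin_volume(cv, 2L)$data == 3))
  odd <- density_volume(array(1, c(9, 8, 8)), 1)
  expect_warning(bin_volume(odd, 2L), "cropped")
})

test_that("binning a detector-resolution volume reproduces the working pixel size", {
  # 4k camera at 25000x: detector pixel ~0.435 nm, printed as 0.43;
  # binning by 2 gives 0.87 at the printed precision
  vol <- density_volume(array(0.0, c(8, 8, 8)), 0.4349)
  expect_equal(round(vol$voxel_size, 2), 0.43)
  expect_equal(round(bin_volume(vol, 2L)$voxel_size, 2), 0.87)
})
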