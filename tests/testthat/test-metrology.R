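noiseless_net <- function(seed = 7, shape = c(96L, 112L, 40L)) {
  spec <- make_preset("cryo", shape_voxels = shape, seed = seed, snr = Inf,
                      psf_sigma = 0, missing_wedge_halfangle_deg = 90)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  m <- analyze_roi(img, analysis_roi(group = "cryo"),
                   wall_config(polarity = "dense_dark"))
  list(phantom = ph, measurements = m)
}

test_that("dominant orientation behaves on canonical sets", {
  f <- function(o, l) list(orient = o, length_nm = l)
  expect_equal(dominant_orientation(list(f(c(0, 1, 0), 10), f(c(0, 1, 0), 5))),
               c(0, 1, 0))
  a <- pi / 18
  two <- list(f(unit3(c(0, cos(a), sin(a))), 7),
              f(unit3(c(0, cos(a), -sin(a))), 7))
  expect_equal(dominant_orientation(two), c(0, 1, 0), tolerance = 1e-9)
  one <- list(f(unit3(c(0.1, 0.9, 0.2)), 3))
  expect_equal(dominant_orientation(one), unit3(c(0.1, 0.9, 0.2)),
               tolerance = 1e-9)
  expect_error(dominant_orientation(list()), "empty")
})

test_that("plane sampling is deterministic, ranged, and uniform", {
  roi <- analysis_roi(seed = 4L)
  p1 <- sample_planes(roi, c(0, 1, 0), 2L, dim_zyx = c(40, 100, 40))
  p2 <- sample_planes(roi, c(0, 1, 0), 2L, dim_zyx = c(40, 100, 40))
  expect_identical(p1, p2)
  expect_true(all(p1$position >= 1 + 0.1 * 99 & p1$position <= 1 + 0.9 * 99))
  draws <- unlist(lapply(1:1000, function(s)
    sample_planes(analysis_roi(seed = s), c(0, 1, 0), 2L,
                  dim_zyx = c(40, 100, 40))$position))
  scaled <- (draws - (1 + 0.1 * 99)) / (0.8 * 99)
  expect_gt(stats::ks.test(scaled, "punif")$p.value, 0.01)
  expect_error(sample_planes(roi, c(0, 1, 0), 50L, dim_zyx = c(40, 30, 40)),
               "thinner")
})

test_that("a clean cylinder measures its true diameter", {
  cf <- cylinder_fixture(r_nm = 2.5, vs = 0.87, ny = 64, nzx = 24)
  nv <- normalize_density(cf$volume)
  lab <- threshold_segment(nv, (0.5 - mean(cf$volume$data)) /
                             sd(cf$volume$data))
  g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 5)
  net <- classify_segments(g, lab, classify_params(fibril_min_length = 10))
  planes <- data.frame(id = 1:2, axis = 2, position = c(20, 40),
                       slice = c(20L, 40L))
  dd <- stats::density(as.vector(nv$data), n = 512)
  m <- measure_fibril_diameters(net, nv$data, planes,
                                bg_level = dd$x[which.max(dd$y)])
  expect_equal(nrow(m), 2)
  expect_lt(max(abs(m$value_nm - 5.0)), 0.87)
})

test_that("two parallel cylinders give analytic center and edge distances", {
  fib <- data.frame(z = c(10, 10), y = c(26, 26), x = c(8, 18),
                    uz = 0, uy = 1, ux = 0, radius_nm = 2.5)
  mp <- manual_phantom(fib, shape_voxels = c(28L, 60L, 24L), voxel_size = 1)
  nv <- normalize_density(mp$volume)
  lab <- threshold_segment(nv, (0.5 - mean(mp$volume$data)) /
                             sd(mp$volume$data))
  g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 5)
  net <- classify_segments(g, lab, classify_params(fibril_min_length = 20))
  planes <- data.frame(id = 1, axis = 2, position = 30, slice = 30L)
  dd <- stats::density(as.vector(nv$data), n = 512)
  m <- measure_interfibril_distances(net, nv$data, planes,
                                     bg_level = dd$x[which.max(dd$y)])
  gc <- m$value_nm[m$type == "center_dist"]
  ge <- m$value_nm[m$type == "edge_gap"]
  expect_equal(length(gc), 1)
  expect_lt(abs(gc - 10), 1)
  expect_lt(abs(ge - 5), 1)
})

test_that("pair identity g_c = g_e + (d_i + d_j)/2 holds within a voxel", {
  res <- noiseless_net()
  m <- res$measurements
  pairs <- m[m$type == "center_dist", ]
  gaps <- m[m$type == "edge_gap", ]
  dia <- m[m$type == "diameter", ]
  checked <- 0
  errs <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    ge <- gaps$value_nm[gaps$plane == pairs$plane[r] &
                          gaps$object_i == pairs$object_i[r] &
                          gaps$object_j == pairs$object_j[r]]
    di <- dia$value_nm[dia$plane == pairs$plane[r] &
                         dia$object_i == pairs$object_i[r]]
    dj <- dia$value_nm[dia$plane == pairs$plane[r] &
                         dia$object_i == pairs$object_j[r]]
    if (!length(ge) || !length(di) || !length(dj)) next
    checked <- checked + 1
    errs <- c(errs, abs(pairs$value_nm[r] - ge[1] - (di[1] + dj[1]) / 2))
  }
  expect_gt(checked, 10)
  expect_lt(median(errs), 0.87)       # one voxel, typical pair
  expect_lt(max(errs), 3 * 0.87)      # worst case bounded
})

test_that("a bridge spanning a known gap measures its length", {
  fib <- data.frame(z = c(10, 10), y = c(26, 26), x = c(8, 18),
                    uz = 0, uy = 1, ux = 0, radius_nm = 2.5)
  br <- data.frame(fibril_i = 1, fibril_j = 2, az = 10, ay = 26, ax = 10.5,
                   bz = 10, by = 26, bx = 15.5)     # 5 nm surface gap
  mp <- manual_phantom(fib, br, shape_voxels = c(28L, 60L, 24L),
                       voxel_size = 1, crosslink_diameter = 2.4)
  nv <- normalize_density(mp$volume)
  lab <- threshold_segment(nv, (0.5 - mean(mp$volume$data)) /
                             sd(mp$volume$data))
  g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 5)
  net <- classify_segments(g, lab, classify_params(fibril_min_length = 20))
  dd <- stats::density(as.vector(nv$data), n = 512)
  m <- measure_crosslink_lengths(net, nv$data,
                                 bg_level = dd$x[which.max(dd$y)])
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$value_nm - 5.0), 1.0)
})

test_that("an extracted-preset pipeline yields no cross-links", {
  spec <- make_preset("extracted", shape_voxels = c(96L, 112L, 40L),
                      seed = 5)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  m <- analyze_roi(img, analysis_roi(group = "extracted"), wall_config())
  expect_equal(sum(m$type == "crosslink_len"), 0)
})

test_that("analyze_roi is deterministic and degenerate-safe", {
  spec <- make_preset("cryo", shape_voxels = c(64L, 80L, 36L), seed = 2)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  cfg <- wall_config(polarity = "dense_dark")
  m1 <- analyze_roi(img, analysis_roi(group = "cryo"), cfg)
  m2 <- analyze_roi(img, analysis_roi(group = "cryo"), cfg)
  expect_identical(as.data.frame(m1), as.data.frame(m2))

  set.seed(1)
  flat <- density_volume(array(rnorm(40 * 40 * 40, 0, 1), c(40, 40, 40)), 0.87)
  m0 <- suppressWarnings(analyze_roi(flat, analysis_roi(), wall_config()))
  expect_s3_class(m0, "wall_measurements")
})

test_that("all roi-plane combinations appear and counts scale with planes", {
  spec <- make_preset("cryo", shape_voxels = c(96L, 144L, 40L), seed = 7,
                      snr = Inf, psf_sigma = 0,
                      missing_wedge_halfangle_deg = 90)
  ph <- generate_wall_phantom(spec)
  img <- apply_imaging_model(ph$volume, spec)
  rois <- list(analysis_roi(y = c(1L, 48L), id = "roi1", group = "cryo"),
               analysis_roi(y = c(49L, 96L), id = "roi2", group = "cryo"),
               analysis_roi(y = c(97L, 144L), id = "roi3", group = "cryo"))
  cfg2 <- wall_config(polarity = "dense_dark", k_planes = 2L)
  parts <- lapply(rois, function(r) analyze_roi(img, r, cfg2))
  m <- do.call(rbind, parts)
  combos <- unique(m[m$type == "diameter", c("roi", "plane")])
  expect_equal(nrow(combos), 6)
  cfg4 <- wall_config(polarity = "dense_dark", k_planes = 4L)
  m4 <- analyze_roi(img, rois[[1]], cfg4)
  n2 <- sum(parts[[1]]$type == "diameter")
  n4 <- sum(m4$type == "diameter")
  expect_gt(n4 / n2, 1.5)
  expect_lt(n4 / n2, 2.5)
})
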