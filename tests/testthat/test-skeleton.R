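test_that("thinning keeps a single voxel and centerlines a rod", {
  m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
  sk <- thin3d(m, voxel_size = 1)
  expect_identical(which(sk$mask != 0), which(m != 0))

  rod <- array(0L, c(9, 26, 9)); rod[4:6, 4:23, 4:6] <- 1L
  skr <- thin3d(rod, voxel_size = 1)
  w <- which(skr$mask != 0, arr.ind = TRUE)
  expect_equal(count_components(skr$mask, 26), 1)
  # endpoints within one voxel of the rod end-face centers (5, 4/23, 5)
  ends <- w[w[, 2] %in% range(w[, 2]), , drop = FALSE]
  expect_lte(max(abs(ends[, 1] - 5)), 1)
  expect_lte(max(abs(ends[, 3] - 5)), 1)
  expect_lte(min(w[, 2]) - 4, 1)
  expect_lte(23 - max(w[, 2]), 1)
})

test_that("thinning preserves the loop of a solid torus", {
  d <- c(9L, 24L, 24L)
  arr <- array(0, d)
  th <- seq(0, 2 * pi, length.out = 60)
  ring <- cbind(4, 11.5 + 7 * sin(th), 11.5 + 7 * cos(th))
  segs <- cbind(ring[-nrow(ring), ], ring[-1, ], 1.6, 1)
  arr <- wallfibril3d:::cpp_add_capsules(as.numeric(arr), as.integer(d), segs, 1)
  dim(arr) <- d
  mask <- arr > 0.5
  sk <- thin3d(mask, voxel_size = 1)
  expect_equal(betti1(mask), 1)
  expect_equal(betti1(sk$mask), 1)
  expect_equal(count_components(sk$mask, 26), count_components(mask, 26))
})

test_that("thinning preserves topology on random masks", {
  for (s in 1:12) {
    m <- random_mask(s)
    sk <- thin3d(m, voxel_size = 1)
    expect_equal(count_components(sk$mask, 26), count_components(m, 26),
                 info = paste("components, seed", s))
    expect_equal(euler_characteristic(sk$mask), euler_characteristic(m),
                 info = paste("Euler characteristic, seed", s))
  }
})

test_that("graphs of simple skeletons have the expected shape", {
  path <- array(0L, c(5, 26, 5)); path[3, 4:23, 3] <- 1L
  g <- build_skeleton_graph(thin3d(path, voxel_size = 1))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(length(g$edges), 1)
  expect_equal(g$edges[[1]]$length_nm, 19)

  tj <- array(0L, c(5, 30, 30))
  tj[3, 5:25, 15] <- 1L
  tj[3, 15, 16:25] <- 1L
  gt <- build_skeleton_graph(thin3d(tj, voxel_size = 1))
  expect_equal(nrow(gt$nodes), 4)
  expect_equal(length(gt$edges), 3)

  loop <- array(0L, c(5, 16, 16))
  th <- seq(0, 2 * pi, length.out = 40)
  for (k in seq_along(th))
    loop[3, round(8 + 5 * sin(th[k])), round(8 + 5 * cos(th[k]))] <- 1L
  skl <- list(mask = loop, voxel_size = 1)
  class(skl) <- "skeleton_volume"
  skl$mask <- thin3d(loop, voxel_size = 1)$mask
  gl <- build_skeleton_graph(thin3d(loop, voxel_size = 1))
  expect_equal(length(gl$edges), 1)
  expect_equal(gl$edges[[1]]$n1, gl$edges[[1]]$n2)
})

test_that("non-thin input is rejected", {
  solid <- array(1L, c(6, 6, 6))
  skl <- structure(list(mask = solid, voxel_size = 1),
                   class = "skeleton_volume")
  expect_error(build_skeleton_graph(skl), "not a skeleton")
})

test_that("spur pruning removes twigs but protects components", {
  tj <- array(0L, c(5, 30, 30))
  tj[3, 5:25, 15] <- 1L                    # 20-voxel main path
  tj[3, 15, 16:17] <- 1L                   # 2-voxel twig
  g <- build_skeleton_graph(thin3d(tj, voxel_size = 1))
  expect_identical(prune_spurs(g, 0), g)
  p <- prune_spurs(g, 5)
  expect_equal(length(p$edges), 1)
  expect_gte(p$edges[[1]]$length_nm, 19)
  # a component of only short edges keeps its longest edge
  short <- array(0L, c(5, 12, 12)); short[3, 4:8, 4] <- 1L
  gs <- build_skeleton_graph(thin3d(short, voxel_size = 1))
  ps <- prune_spurs(gs, 50)
  expect_gte(length(ps$edges), 1)
})

test_that("two bridged cylinders classify into fibrils and one cross-link", {
  fib <- data.frame(z = c(10, 10), y = c(26, 26), x = c(8, 18),
                    uz = 0, uy = 1, ux = 0, radius_nm = 2.2)
  br <- data.frame(fibril_i = 1, fibril_j = 2, az = 10, ay = 26, ax = 10.2,
                   bz = 10, by = 26, bx = 15.8)
  mp <- manual_phantom(fib, br, shape_voxels = c(28L, 60L, 24L),
                       voxel_size = 1, crosslink_diameter = 2.4)
  lab <- threshold_segment(normalize_density(mp$volume),
                           (0.5 - mean(mp$volume$data)) / sd(mp$volume$data))
  g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 5)
  net <- classify_segments(g, lab, classify_params(fibril_min_length = 20))
  expect_equal(length(net$fibrils), 2)
  expect_equal(length(net$crosslinks), 1)
  expect_setequal(c(net$crosslinks[[1]]$fibril_i,
                    net$crosslinks[[1]]$fibril_j), c(1, 2))
})

test_that("short isolated segments are unclassified", {
  short <- array(0L, c(9, 16, 9)); short[4:5, 5:12, 4:5] <- 1L
  lab <- threshold_segment(density_volume(short + 0, 1), 0.5)
  g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 0)
  net <- suppressWarnings(classify_segments(g, lab, classify_params()))
  expect_equal(length(net$fibrils), 0)
  expect_equal(length(net$crosslinks), 0)
  expect_gte(net$n_unclassified, 1)
})

test_that("distance-transform radii are accurate on clean cylinders", {
  for (r in c(1.5, 2.5, 4)) {
    cf <- cylinder_fixture(r_nm = r, vs = 1, ny = 40, nzx = 8 + 2 * ceiling(r) * 2)
    lab <- threshold_segment(normalize_density(cf$volume),
                             (0.5 - mean(cf$volume$data)) / sd(cf$volume$data))
    g <- prune_spurs(build_skeleton_graph(thin3d(lab)), 5)
    net <- classify_segments(g, lab,
                             classify_params(fibril_min_length = 10))
    expect_equal(length(net$fibrils), 1)
    mid <- net$fibrils[[1]]$radii_nm
    mid <- mid[round(length(mid) / 3):round(2 * length(mid) / 3)]
    expect_lte(abs(median(mid) - r), 0.5 + 1e-9)
  }
})
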