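# Independent oracles and fixture builders used across the suite.

# Euler characteristic of the cubical complex of a binary 3D mask, by
# counting vertices, edges, faces and cubes of the union of unit voxels.
# Independent of every package kernel (pure array shifts).
euler_characteristic <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  # presence grids for cells of each dimension
  occ <- function(dzs, dys, dxs) {
    out <- array(FALSE, d + 1)
    for (dz in dzs) for (dy in dys) for (dx in dxs)
      out <- out | pad[(1:(d[1] + 1)) + dz, (1:(d[2] + 1)) + dy,
                       (1:(d[3] + 1)) + dx]
    sum(out)
  }
  v <- occ(0:1, 0:1, 0:1)                     # vertices
  e <- occ(0:1, 0:1, 0) + occ(0:1, 0, 0:1) + occ(0, 0:1, 0:1)
  f <- occ(0:1, 0, 0) + occ(0, 0:1, 0) + occ(0, 0, 0:1)
  c3 <- sum(pad)
  v - e + f - c3
}

# connected components of a binary mask by igraph (independent of the
# package's labeling kernel); connectivity 26 or 6
count_components <- function(mask, connectivity = 26) {
  idx <- which(mask != 0)
  if (!length(idx)) return(0L)
  d <- dim(mask)
  z <- (idx - 1) %% d[1]
  y <- ((idx - 1) %/% d[1]) %% d[2]
  x <- (idx - 1) %/% (d[1] * d[2])
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
    ok <- zz >= 0 & zz < d[1] & yy >= 0 & yy < d[2] & xx >= 0 & xx < d[3]
    lin <- zz + d[1] * (yy + d[2] * xx) + 1
    m <- match(lin[ok], idx)
    src <- which(ok)[!is.na(m)]
    dst <- m[!is.na(m)]
    keep <- src < dst
    edges <- rbind(edges, cbind(src[keep], dst[keep]))
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}

# Betti-1 (independent loops) of a mask from components, cavities and the
# Euler characteristic: b1 = b0 + b2 - chi, with b2 = bounded background
# 6-components
betti1 <- function(mask) {
  d <- dim(mask)
  b0 <- count_components(mask, 26)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  bgcomp <- count_components(!pad, 6)
  b2 <- bgcomp - 1L
  b0 + b2 - euler_characteristic(mask)
}

# random small blob/rod masks for topology tests
random_mask <- function(seed, d = c(18L, 18L, 18L)) {
  set.seed(seed)
  arr <- array(0, d)
  n <- sample(2:4, 1)
  segs <- t(replicate(n, {
    p0 <- runif(3, 3, d - 3)
    p1 <- pmin(pmax(p0 + runif(3, -8, 8), 2), d - 2)
    c(p0, p1, runif(1, 1.2, 2.4), 1)
  }))
  arr <- wallfibril3d:::cpp_add_capsules(as.numeric(arr), as.integer(d),
                                         segs, 1.0)
  dim(arr) <- d
  arr > 0.5
}

# rasterize an axis-aligned cylinder along y, returning volume + truth
cylinder_fixture <- function(r_nm = 2.5, vs = 0.87, ny = 64L, nzx = 24L,
                             center = NULL) {
  if (is.null(center)) center <- floor((nzx - 1) / 2) * vs
  fib <- data.frame(z = center, y = (ny - 1) / 2 * vs, x = center,
                    uz = 0, uy = 1, ux = 0, radius_nm = r_nm)
  manual_phantom(fib, shape_voxels = c(nzx, ny, nzx), voxel_size = vs)
}

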