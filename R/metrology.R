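#' Analysis region of interest
#'
#' A rectangular sub-volume scheduled for analysis, with a group label used
#' in downstream comparisons. Bounds are 1-based inclusive voxel ranges in
#' (z, y, x) order; `NULL` means the full extent.
#'
#' @param z,y,x length-2 integer ranges or NULL.
#' @param group group label (e.g. "cryo", "WT").
#' @param id ROI identifier.
#' @param seed seed for the ROI's plane sampling.
#' @return an `analysis_roi`.
#' @export
analysis_roi <- function(z = NULL, y = NULL, x = NULL, group = "",
                         id = "roi1", seed = 1L) {
  structure(list(z = z, y = y, x = x, group = group, id = id,
                 seed = as.integer(seed)),
            class = "analysis_roi")
}

roi_crop <- function(vol, roi) {
  d <- dim(vol$data)
  rz <- roi$z %||% c(1L, d[1]); ry <- roi$y %||% c(1L, d[2])
  rx <- roi$x %||% c(1L, d[3])
  if (rz[1] < 1 || rz[2] > d[1] || ry[1] < 1 || ry[2] > d[2] ||
      rx[1] < 1 || rx[2] > d[3])
    stop("ROI bounds outside source volume")
  density_volume(vol$data[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE],
                 vol$voxel_size, vol$provenance)
}

#' Dominant fibril orientation
#'
#' Principal eigenvector of the length-weighted sum of fibril orientation
#' outer products, sign-fixed to a positive first nonzero component.
#'
#' @param fibrils a `wall_network` or a list of fibril records with `orient`
#'   and `length_nm`.
#' @return unit 3-vector in (z, y, x) component order.
#' @export
dominant_orientation <- function(fibrils) {
  if (inherits(fibrils, "wall_network")) fibrils <- fibrils$fibrils
  if (!length(fibrils)) stop("empty fibril set has no orientation")
  M <- matrix(0, 3, 3)
  for (f in fibrils) M <- M + f$length_nm * tcrossprod(f$orient)
  fix_sign(eigen(M, symmetric = TRUE)$vectors[, 1])
}

#' Sample cross-sectional planes
#'
#' Draws `k` distinct planes orthogonal to the fibril axis, positions
#' uniform over the central 80% of the ROI extent along that axis.
#' Deterministic for a fixed seed. Planes are realized as lattice slices
#' along the array axis closest to `axis`.
#'
#' @param roi an `analysis_roi` (bounds used for the extent).
#' @param axis unit 3-vector (z, y, x); typically the dominant orientation.
#' @param k number of planes (>= 1, default 2).
#' @param seed RNG seed; defaults to the ROI's.
#' @param dim_zyx dimensions of the (cropped) volume the slices index into.
#' @return data.frame with plane `id`, `axis` (array axis index 1-3),
#'   `position` (continuous, voxels) and `slice` (integer index).
#' @export
sample_planes <- function(roi, axis = c(0, 1, 0), k = 2L, seed = roi$seed,
                          dim_zyx) {
  if (k < 1) stop("k must be >= 1")
  a <- which.max(abs(axis))
  n <- dim_zyx[a]
  if (n < k + 2) stop("ROI thinner than the requested number of planes")
  lo <- 1 + 0.1 * (n - 1); hi <- 1 + 0.9 * (n - 1)
  with_seed(seed, {
    pos <- numeric(0)
    for (i in 1:100) {
      pos <- unique(c(pos, stats::runif(k, lo, hi)))
      if (length(unique(round(pos))) >= k) break
    }
    pos <- pos[!duplicated(round(pos))][seq_len(k)]
    data.frame(id = seq_len(k), axis = a, position = pos,
               slice = as.integer(round(pos)))
  })
}

# fibril-plane crossings: where the path's coordinate along array axis a
# straddles the slice index; returns crossing points (continuous voxel
# coords, 0-based) and tangents
plane_crossings <- function(net, plane, oblique_max_deg = 20) {
  a <- plane$axis
  out <- list()
  nrml <- c(0, 0, 0); nrml[a] <- 1
  c0 <- plane$slice - 1      # paths are 0-based
  for (fi in seq_along(net$fibrils)) {
    f <- net$fibrils[[fi]]
    p <- f$path
    if (nrow(p) < 2) next
    s <- p[, a] - c0
    # sign changes, counting a zero-run (vertices exactly on the plane) once
    sgn <- sign(s)
    cross <- integer(0)
    last <- 0
    for (i in seq_along(sgn)) {
      if (sgn[i] == 0) next
      if (last != 0 && sgn[i] != last)
        cross <- c(cross, max(which(sgn[seq_len(i - 1)] != 0)))
      last <- sgn[i]
    }
    for (i in cross) {
      t <- s[i] / (s[i] - s[i + 1])
      pt <- p[i, ] + t * (p[i + 1, ] - p[i, ])
      # smooth the transverse coordinates over a short path window: the
      # voxel skeleton wobbles by 1-2 voxels and the raw crossing position
      # would inherit that jitter
      iw <- max(1, i - 3):min(nrow(p), i + 4)
      if (length(iw) >= 3) {
        ctr <- colMeans(p[iw, , drop = FALSE])
        pt[-a] <- ctr[-a]
      }
      i0 <- max(1, i - 1); i1 <- min(nrow(p), i + 2)
      tang <- p[i1, ] - p[i0, ]
      if (sum(tang^2) == 0) next
      tang <- unit3(as.numeric(tang))
      if (abs(sum(tang * nrml)) < cos(70 * pi / 180)) next  # oblique: skip
      ri <- f$radii_nm[i]
      out[[length(out) + 1L]] <- list(fibril = fi, point = pt, tangent = tang,
                                      layer = f$layer, radius_nm = ri)
    }
  }
  out
}

#' Measure fibril cross-sectional diameters
#'
#' For each fibril-plane crossing, the diameter is the full width of the
#' density profile at the local half-maximum level, measured along the
#' in-plane direction perpendicular to the fibril - the visible width an
#' operator measures in a tomogram slice. The level is
#' `(local peak + background mode)/2 + delta`, so the global threshold
#' offset `delta` shifts the measured surfaces exactly as re-thresholding
#' would, while the measurement is immune to beam-axis elongation and to
#' where the voxel lattice falls. Crossings whose tangent lies within 20
#' degrees of the plane are skipped (oblique sections would inflate the
#' diameter).
#'
#' @param net a `wall_network`.
#' @param intensity filtered density array (SD units), same grid.
#' @param planes data.frame from [sample_planes()].
#' @param bg_level background mode of `intensity` (SD units).
#' @param delta surface-level offset (SD units).
#' @param roi_id,group labels recorded per row.
#' @return measurement data.frame rows (type "diameter").
#' @export
measure_fibril_diameters <- function(net, intensity, planes, bg_level = 0,
                                     delta = 0, roi_id = "roi1", group = "") {
  vs <- net$voxel_size
  rows <- list()
  for (pli in seq_len(nrow(planes))) {
    pl <- planes[pli, ]
    crs <- plane_crossings(net, pl)
    for (cr in crs) {
      # in-plane direction perpendicular to the fibril (the visible width
      # direction in a slice image, avoiding the beam axis)
      u <- cross3v(cr$tangent, c(1, 0, 0))
      if (vec3_norm(u) < 0.2) u <- cross3v(cr$tangent, c(0, 0, 1))
      u <- unit3(u)
      w <- profile_halfmax_width(intensity, cr$point, u,
                                 max_r = cr$radius_nm / vs + 4,
                                 bg_level = bg_level, delta = delta)
      if (is.na(w) || w <= 0.5) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = "diameter", value_nm = w * vs,
        plane = pl$id, roi = roi_id, group = group,
        object_i = cr$fibril, object_j = NA_integer_)
    }
  }
  bind_measurements(rows)
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# trilinear interpolation of a 3D array at fractional 0-based (z,y,x)
# coordinates given as an n x 3 matrix; coordinates clamped to the grid
trilinear <- function(arr, pts) {
  d <- dim(arr)
  pz <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  py <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  px <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  z0 <- pmin(floor(pz), d[1] - 2); y0 <- pmin(floor(py), d[2] - 2)
  x0 <- pmin(floor(px), d[3] - 2)
  fz <- pz - z0; fy <- py - y0; fx <- px - x0
  idx <- function(dz, dy, dx)
    arr[(z0 + dz) + 1 + d[1] * ((y0 + dy) + d[2] * (x0 + dx))]
  idx(0, 0, 0) * (1 - fz) * (1 - fy) * (1 - fx) +
    idx(1, 0, 0) * fz * (1 - fy) * (1 - fx) +
    idx(0, 1, 0) * (1 - fz) * fy * (1 - fx) +
    idx(0, 0, 1) * (1 - fz) * (1 - fy) * fx +
    idx(1, 1, 0) * fz * fy * (1 - fx) +
    idx(1, 0, 1) * fz * (1 - fy) * fx +
    idx(0, 1, 1) * (1 - fz) * fy * fx +
    idx(1, 1, 1) * fz * fy * fx
}

# full width of the density profile through `center` along unit vector `u`
# at the local half-maximum level (peak vs bg_level), in voxels, with a
# first-order curvature correction: the half-height contour of a
# Gaussian-blurred convex cross-section drifts inward by sigma^2 / (2 r),
# with sigma estimated from the profile's steepest flank
profile_halfmax_width <- function(arr, center, u, max_r, bg_level, delta = 0,
                                  step = 0.25) {
  tt <- seq(-max_r, max_r, by = step)
  pts <- cbind(center[1] + tt * u[1], center[2] + tt * u[2],
               center[3] + tt * u[3])
  prof <- trilinear(arr, pts)
  mid <- which.min(abs(tt))
  near <- abs(tt) <= 1
  peak <- max(prof[near])
  if (peak <= bg_level) return(NA_real_)
  # local background: the missing wedge depresses the surround of bright
  # features below the global mode, so reference each profile to its own
  # shoulders (minima on either flank)
  two_pass <- function(bg) {
    level <- (peak + bg) / 2
    if (peak <= level) return(NULL)
    iL <- mid
    while (iL > 1 && prof[iL - 1] > level) iL <- iL - 1
    iR <- mid
    while (iR < length(tt) && prof[iR + 1] > level) iR <- iR + 1
    tl <- if (iL == 1) tt[1] else
      tt[iL] - step * (prof[iL] - level) / (prof[iL] - prof[iL - 1])
    tr <- if (iR == length(tt)) tt[length(tt)] else
      tt[iR] + step * (prof[iR] - level) / (prof[iR] - prof[iR + 1])
    list(tl = tl, tr = tr, level = level)
  }
  p1 <- two_pass(bg_level)
  if (is.null(p1)) return(NA_real_)
  left <- prof[tt < p1$tl]; right <- prof[tt > p1$tr]
  # a low quantile of the shoulders rather than their minimum: robust to a
  # single deep wedge lobe, so sparse and crowded surroundings reference
  # comparably
  bg_loc <- if (length(left) && length(right))
    (stats::quantile(left, 0.2, names = FALSE) +
       stats::quantile(right, 0.2, names = FALSE)) / 2 else bg_level
  bg_loc <- min(bg_loc, bg_level)      # never raise above the global mode
  p2 <- two_pass(bg_loc)
  if (is.null(p2)) return(NA_real_)
  w <- p2$tr - p2$tl
  slope <- max(abs(diff(prof[tt >= p2$tl - 1 & tt <= p2$tr + 1]))) / step
  d0 <- deblur_disk_diameter(w, peak - bg_loc, slope)
  # threshold-sensitivity offset: raising the surface level by delta erodes
  # each surface by delta / slope (first-order), as re-thresholding would
  d0 - 2 * sign(delta) * min(abs(delta) / max(slope, 1e-6), 1.5)
}

# ---- blurred-disk deblurring -----------------------------------------------
# A fibril cross-section is modeled as a disk of radius r observed through
# an isotropic Gaussian blur sigma. Its radial profile is
#   I(t) = A * int_0^r rho exp(-(rho^2+t^2)/(2 sigma^2)) I0(rho t/sigma^2) drho / sigma^2.
# The scale-invariant observable h = FWHM * max-slope / peak depends only on
# x = r / sigma, so (FWHM, peak, slope) determine r without knowing the blur.
# Below x ~ 0.9 the profile is blur-dominated and h saturates; x is clamped
# there (sub-resolution sections cannot be sized, mirroring the ~2 nm
# resolution limit of the imaging).
disk_blur_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    xs <- exp(seq(log(0.9), log(8), length.out = 60))
    rho <- seq(0, 1, length.out = 200)
    prof_fun <- function(x, t) {
      rr <- rho * x
      f <- rr * exp(-(rr^2 + t^2) / 2) * besselI(rr * t, 0, expon.scaled = TRUE) *
        exp(rr * t)
      sum(f) * (x / 200)
    }
    h <- tw <- smm <- numeric(length(xs))
    for (k in seq_along(xs)) {
      x <- xs[k]
      ts <- seq(0, x + 5, by = 0.02)
      I <- vapply(ts, function(t) prof_fun(x, t), numeric(1))
      pk <- I[1]
      half_i <- which(I <= pk / 2)[1]
      t_half <- ts[half_i] - 0.02 * (pk / 2 - I[half_i]) /
        (I[half_i - 1] - I[half_i])
      slope <- max(abs(diff(I))) / 0.02
      h[k] <- 2 * t_half * slope / pk
      tw[k] <- t_half / x           # measured half-width per true radius
      smm[k] <- slope / pk          # max slope per peak, in sigma units
    }
    tab <<- list(x = xs, h = h, tw = tw, smm = smm)
    tab
  }
})

# invert (width, amplitude, slope) to the true disk diameter, in the same
# length unit as `w`
deblur_disk_diameter <- function(w, A, slope) {
  if (!is.finite(w) || w <= 0 || A <= 0 || slope <= 0) return(w)
  tb <- disk_blur_table()
  h_obs <- w * slope / A
  h_obs <- min(max(h_obs, min(tb$h)), max(tb$h))
  x <- stats::approx(tb$h, tb$x, xout = h_obs, ties = "ordered")$y
  twx <- stats::approx(tb$x, tb$tw, xout = x, ties = "ordered")$y
  w / twx        # measured width = tw * true diameter
}

#' Measure inter-fibril distances in cross-sectional planes
#'
#' Within each plane, fibril crossings are paired with their nearest
#' neighbors in the same lamella: crossings are ordered along the lamella
#' and consecutive crossings (height difference below the lamella scale)
#' form mutual neighbor pairs, up to a robust cap against pairs that span a
#' missed fibril. Per pair two rows are emitted: `center_dist`
#' (center-to-center distance of the crossing points) and `edge_gap` (the
#' surface-to-surface distance along the center line, surfaces at the local
#' half-maximum density level plus `delta`), both in nm.
#'
#' @param net a `wall_network`.
#' @param intensity filtered density array (SD units), same grid.
#' @param planes data.frame from [sample_planes()].
#' @param bg_level background mode of `intensity` (SD units).
#' @param delta surface-level offset (SD units).
#' @param pairing_max maximum center distance considered a neighbor pair, nm.
#' @param roi_id,group labels recorded per row.
#' @return measurement data.frame rows (types "center_dist", "edge_gap").
#' @export
measure_interfibril_distances <- function(net, intensity, planes,
                                          bg_level = 0, delta = 0,
                                          pairing_max = 45, roi_id = "roi1",
                                          group = "") {
  vs <- net$voxel_size
  rows <- list()
  for (pli in seq_len(nrow(planes))) {
    pl <- planes[pli, ]
    crs <- plane_crossings(net, pl)
    if (length(crs) < 2) next
    pts <- t(vapply(crs, function(cr) cr$point, numeric(3)))
    lay <- vapply(crs, function(cr) cr$layer, integer(1))
    fid <- vapply(crs, function(cr) cr$fibril, numeric(1))
    # in-plane slice coordinates (drop the plane axis)
    keep_ax <- setdiff(1:3, pl$axis)
    P <- pts[, keep_ax, drop = FALSE]
    n <- nrow(P)
    # neighbor pairs: a crossing's in-lamella neighbors are the nearest
    # crossings on either side along the lamella (largest in-plane spread
    # direction) whose height differs by at most dz_max - a local criterion
    # that survives noisy lamella assignment. Pairing each crossing with the
    # neighbor on EACH side avoids the selection bias of keeping only the
    # closer one.
    spread <- apply(P, 2, stats::var)
    axl <- which.max(spread)            # along-lamella coordinate
    axh <- 3 - axl                      # height coordinate
    dz_max <- 5 / vs                    # voxels
    ord <- order(P[, axl])
    cand <- NULL
    for (oi in seq_along(ord)) {
      i <- ord[oi]
      for (oj in seq_along(ord)) {
        if (oj <= oi) next
        j <- ord[oj]
        if (abs(P[i, axh] - P[j, axh]) > dz_max) next
        cand <- rbind(cand, c(i, j))
        break                            # nearest right-hand neighbor only
      }
    }
    if (is.null(cand)) next
    # a crossing the segmentation missed would otherwise produce one pair
    # spanning two true gaps; such doubled pairs are rejected as robust
    # outliers against the plane's median neighbor distance
    gcs <- vapply(seq_len(nrow(cand)), function(r)
      sqrt(sum((P[cand[r, 1], ] - P[cand[r, 2], ])^2)) * vs, numeric(1))
    gc_cap <- min(pairing_max, 1.8 * stats::median(gcs))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (fid[i] == fid[j]) next
      gc <- gcs[r]
      if (!is.finite(gc) || gc > gc_cap) next
      ge <- profile_surface_gap(intensity, pts[i, ], pts[j, ], bg_level,
                                delta,
                                r_a = crs[[i]]$radius_nm / vs,
                                r_b = crs[[j]]$radius_nm / vs)
      if (is.na(ge)) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = c("center_dist", "edge_gap"), value_nm = c(gc, ge * vs),
        plane = pl$id, roi = roi_id, group = group,
        object_i = fid[i], object_j = fid[j])
    }
  }
  bind_measurements(rows)
}

# surface-to-surface distance (voxels) along the line between two crossing
# centers: each surface is where the profile drops to the local
# half-maximum level of its own fibril (plus delta)
profile_surface_gap <- function(arr, pa, pb, bg_level, delta = 0,
                                r_a = 2, r_b = 2, step = 0.25) {
  u <- pb - pa
  len <- vec3_norm(u)
  if (len < 1) return(NA_real_)
  u <- u / len
  tt <- seq(0, len, by = step)
  pts <- cbind(pa[1] + tt * u[1], pa[2] + tt * u[2], pa[3] + tt * u[3])
  prof <- trilinear(arr, pts)
  n <- length(tt)
  peak_a <- max(prof[tt <= 1]); peak_b <- max(prof[tt >= len - 1])
  # reference the half level to the background (where the wedge depresses
  # the surround, the valley floor is used); if something brighter than
  # that level spans the whole gap (a dense bridge), fall back to levels
  # referenced to the bridge density itself
  valley <- min(prof)
  # a flat profile (bridge as dense as the fibrils, no blur) carries no
  # surface information; signal that so the caller can fall back to the
  # geometric chord estimate
  if (min(peak_a, peak_b) - valley <
      0.25 * max(min(peak_a, peak_b) - bg_level, 1e-9))
    return(NA_real_)
  bg_loc <- min(valley, bg_level)
  walk <- function(lev_a, lev_b) {
    if (peak_a <= lev_a || peak_b <= lev_b) return(NULL)
    ipa <- which.max(ifelse(tt <= 1, prof, -Inf))
    ipb <- which.max(ifelse(tt >= len - 1, prof, -Inf))
    ia <- ipa
    while (ia < n && prof[ia + 1] > lev_a) ia <- ia + 1
    ib <- ipb
    while (ib > 1 && prof[ib - 1] > lev_b) ib <- ib - 1
    if (ia >= ib) return(list(touch = TRUE))
    fa <- (prof[ia] - lev_a) / max(prof[ia] - prof[ia + 1], 1e-9)
    fb <- (prof[ib] - lev_b) / max(prof[ib] - prof[ib - 1], 1e-9)
    list(touch = FALSE, ta = tt[ia] + step * min(max(fa, 0), 1),
         tb = tt[ib] - step * min(max(fb, 0), 1))
  }
  ref <- bg_loc
  w <- walk((peak_a + bg_loc) / 2, (peak_b + bg_loc) / 2)
  if (is.null(w)) return(NA_real_)
  if (w$touch && valley > bg_level) {
    ref <- valley
    w <- walk((peak_a + valley) / 2, (peak_b + valley) / 2)
  }
  if (is.null(w) || w$touch) return(0.25)
  ta <- w$ta; tb <- w$tb
  if (ta >= tb) return(0.25)
  # an intervening density peak means the pair spans a third (possibly
  # faintly detected) fibril: not a neighbor gap, reject
  interior <- tt > ta + 1.2 & tt < tb - 1.2
  if (any(interior) &&
      max(prof[interior]) >= max((peak_a + bg_loc) / 2, (peak_b + bg_loc) / 2))
    return(NA_real_)
  # the half-level surface of a blurred convex section drifts inward,
  # widening the apparent gap; undo the drift on each side using the disk
  # blur model, each fibril's radius, and the flank slope at its crossing
  near_a <- tt >= ta - 2 & tt <= ta + 2
  near_b <- tt >= tb - 2 & tt <= tb + 2
  sa <- if (sum(near_a) > 2) max(abs(diff(prof[near_a]))) / step else 0
  sb <- if (sum(near_b) > 2) max(abs(diff(prof[near_b]))) / step else 0
  da <- surface_drift(peak_a - ref, sa, r_a)
  db <- surface_drift(peak_b - ref, sb, r_b)
  # first-order threshold-sensitivity response: a higher surface level
  # recedes both surfaces into their fibrils, widening the gap
  dsh <- sign(delta) * (min(abs(delta) / max(sa, 1e-6), 1.5) +
                          min(abs(delta) / max(sb, 1e-6), 1.5))
  max(tb - ta - da - db + dsh, 0.25)
}

# inward drift r*(1 - tw(x)) of a half-level surface for a disk of radius
# r (voxels) seen at blur sigma, with sigma estimated from peak amplitude P
# and max flank slope S via a short fixed-point iteration on x = r/sigma
surface_drift <- function(P, S, r) {
  if (!is.finite(P) || !is.finite(S) || P <= 0 || S <= 0 || r <= 0) return(0)
  tb <- disk_blur_table()
  x <- 2
  for (i in 1:3) {
    smm <- stats::approx(tb$x, tb$smm, xout = min(max(x, min(tb$x)), max(tb$x)),
                         ties = "ordered")$y
    sigma <- max((P / S) * smm, 1e-3)
    x <- r / sigma
  }
  x <- min(max(x, min(tb$x)), max(tb$x))
  twx <- stats::approx(tb$x, tb$tw, xout = x, ties = "ordered")$y
  min(max(r * (1 - twx), 0), 1.5)
}

#' Measure cross-link lengths
#'
#' Per classified cross-link, the surface-to-surface length between its two
#' host fibrils along the bridge: with `intensity` supplied, the same
#' local-half-maximum profile estimator used for edge gaps is applied
#' between the two attachment junctions; otherwise the classification's
#' chord-minus-radii estimate is reported. Bridges with both endpoints on
#' the same fibril were excluded at classification.
#'
#' @param net a `wall_network`.
#' @param intensity optional filtered density array (SD units).
#' @param bg_level background mode of `intensity`.
#' @param delta surface-level offset (SD units).
#' @param roi_id,group labels recorded per row.
#' @return measurement data.frame rows (type "crosslink_len").
#' @export
measure_crosslink_lengths <- function(net, intensity = NULL, bg_level = 0,
                                      delta = 0, roi_id = "roi1",
                                      group = "") {
  vs <- net$voxel_size
  rows <- lapply(net$crosslinks, function(cl) {
    val <- cl$length_nm
    if (!is.null(intensity)) {
      ge <- profile_surface_gap(intensity, cl$end_a, cl$end_b, bg_level,
                                delta, r_a = cl$r_a / vs, r_b = cl$r_b / vs)
      if (!is.na(ge)) val <- ge * vs
    }
    data.frame(type = "crosslink_len", value_nm = val, plane = NA_integer_,
               roi = roi_id, group = group, object_i = cl$fibril_i,
               object_j = cl$fibril_j)
  })
  bind_measurements(rows)
}

bind_measurements <- function(rows) {
  if (!length(rows))
    return(structure(data.frame(type = character(), value_nm = numeric(),
                                plane = integer(), roi = character(),
                                group = character(), object_i = numeric(),
                                object_j = numeric()),
                     class = c("wall_measurements", "data.frame")))
  out <- do.call(rbind, rows)
  class(out) <- c("wall_measurements", "data.frame")
  out
}

#' Analysis configuration
#'
#' @param route segmentation route: "threshold" (operator-style global
#'   threshold with sensitivity offset `delta`) or "auto" (structure-tensor
#'   orientation smoothing plus gradient-weighted contour-spectrum isovalue).
#' @param polarity density polarity for [normalize_density()].
#' @param delta threshold offset in SD units added to the base threshold.
#' @param prefilter_sigma light isotropic Gaussian (nm) applied before NAD;
#'   suppresses white noise cheaply so the diffusion works at a contrast
#'   where its edge protection is meaningful. 0 disables.
#' @param filter [diffusion_params()] list for the NAD stage.
#' @param min_voxels speck-removal size for [clean_components()].
#' @param spur_min_len spur-pruning length, nm.
#' @param classify [classify_params()] list.
#' @param k_planes cross-sectional planes per ROI.
#' @param pairing_max neighbor-pairing cap, nm.
#' @param sigma_along,sigma_across orientation-smoothing scales, nm
#'   (auto route).
#' @param seed seed for plane sampling.
#' @return config list.
#' @export
wall_config <- function(route = c("threshold", "auto"),
                        polarity = c("dense_bright", "dense_dark"),
                        delta = 0, prefilter_sigma = 0.87,
                        filter = diffusion_params(),
                        min_voxels = 27L, spur_min_len = 6,
                        classify = classify_params(), k_planes = 2L,
                        pairing_max = 45, sigma_along = 2.0,
                        sigma_across = 0.8, seed = 1L) {
  list(route = match.arg(route), polarity = match.arg(polarity),
       delta = delta, prefilter_sigma = prefilter_sigma,
       filter = filter, min_voxels = as.integer(min_voxels),
       spur_min_len = spur_min_len, classify = classify,
       k_planes = as.integer(k_planes), pairing_max = pairing_max,
       sigma_along = sigma_along, sigma_across = sigma_across,
       seed = as.integer(seed))
}

#' Analyze one region of interest end to end
#'
#' Runs the full measurement pipeline on an ROI: normalize, NAD filter
#' (plus orientation smoothing on the automated route), threshold (operator
#' stand-in via Otsu's criterion, or contour-spectrum isovalue), component
#' cleaning, thinning, graph building, spur pruning, classification, plane
#' sampling, and the diameter / spacing / cross-link measurements.
#' Deterministic for fixed volume, config and seed.
#'
#' @param vol a [density_volume] (raw, un-normalized).
#' @param roi an [analysis_roi()].
#' @param config a [wall_config()] list.
#' @return a `wall_measurements` data.frame; attribute `provenance` records
#'   parameters, seed, the resolved threshold and per-stage counts;
#'   attribute `network` holds the classified `wall_network`.
#' @export
analyze_roi <- function(vol, roi = analysis_roi(), config = wall_config()) {
  stopifnot(inherits(vol, "density_volume"))
  stage <- "crop"
  res <- tryCatch({
    sub <- roi_crop(vol, roi)
    vs <- sub$voxel_size
    stage <- "normalize"
    nrm <- normalize_density(sub, config$polarity)
    stage <- "filter"
    if ((config$prefilter_sigma %||% 0) > 0) {
      s <- config$prefilter_sigma / vs
      pre <- cpp_gauss3d(as.numeric(nrm$data), as.integer(dim(nrm$data)),
                         rep(s, 3))
      dim(pre) <- dim(nrm$data)
      nrm <- density_volume(pre, vs, nrm$provenance)
    }
    flt <- nad_filter(nrm, config$filter)
    stage <- "threshold"
    if (config$route == "auto") {
      tf <- compute_structure_tensor(flt)
      flt <- orientation_smooth(flt, tf, config$sigma_along,
                                config$sigma_across)
    }
    plan <- threshold_plan(flt$data)
    cs <- contour_spectrum(flt, 32)
    plan$meas <- select_isovalue(cs)
    plan$hi <- plan$meas
    plan$lo <- plan$meas - 1.2 * plan$s_lo
    thr <- plan$meas + config$delta
    stage <- "segment"
    # detection is delta-independent: the sensitivity offset moves the
    # measurement surfaces, as re-picking the operator threshold would,
    # without changing which objects are found
    lab <- hysteresis_segment(flt, plan$lo, plan$hi)
    lab <- clean_components(lab, config$min_voxels)
    mmask <- lab$labels > 0 & flt$data > thr
    stage <- "skeletonize"
    sk <- thin3d(lab)
    g <- build_skeleton_graph(sk)
    g <- prune_spurs(g, config$spur_min_len)
    stage <- "classify"
    net <- suppressWarnings(classify_segments(g, lab, config$classify, mmask,
                                              intensity = flt$data,
                                              core_level = plan$meas))
    stage <- "measure"
    if (length(net$fibrils)) {
      dom <- dominant_orientation(net)
      planes <- sample_planes(roi, dom, config$k_planes,
                              seed = config$seed + roi$seed,
                              dim_zyx = dim(lab$labels))
      m <- rbind(
        measure_fibril_diameters(net, flt$data, planes, plan$bg_mode,
                                 config$delta, roi$id, roi$group),
        measure_interfibril_distances(net, flt$data, planes, plan$bg_mode,
                                      config$delta, config$pairing_max,
                                      roi$id, roi$group),
        measure_crosslink_lengths(net, flt$data, plan$bg_mode, config$delta,
                                  roi$id, roi$group))
    } else {
      m <- bind_measurements(list())
      planes <- NULL
    }
    class(m) <- c("wall_measurements", "data.frame")
    attr(m, "provenance") <- list(
      roi = unclass(roi), config = config, threshold = thr,
      counts = list(components = lab$n_components,
                    removed = attr(lab, "removed"),
                    fibrils = length(net$fibrils),
                    crosslinks = length(net$crosslinks),
                    unclassified = net$n_unclassified,
                    measurements = nrow(m)))
    attr(m, "network") <- net
    m
  }, error = function(e) {
    stop("analyze_roi failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
summary.wall_measurements <- function(object, ...) {
  types <- unique(object$type)
  out <- do.call(rbind, lapply(types, function(tp) {
    v <- object$value_nm[object$type == tp]
    data.frame(type = tp, n = length(v), mean_nm = mean(v),
               sd_nm = stats::sd(v), min_nm = min(v), max_nm = max(v))
  }))
  out
}
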