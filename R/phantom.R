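#' Phantom specification for a layered cell-wall fibril network
#'
#' Collects all generator parameters: geometry of the fibril network
#' (diameters, within-layer edge gaps, lamella spacing, orientation jitter,
#' cross-link population) and the imaging model (contrast mode, SNR, PSF,
#' missing wedge). All physical quantities are in nm. Distributions are
#' truncated normals: diameters are floored at 2.2 nm and gaps/cross-link
#' lengths at 2.0 nm, matching the smallest measurements such networks show.
#'
#' @param shape_voxels integer triple (nx, ny, nz); the common fibril axis is
#'   y, the beam axis is z.
#' @param voxel_size isotropic voxel size, nm.
#' @param fibril_diameter_mean,fibril_diameter_sd fibril diameter moments, nm.
#' @param edge_gap_mean,edge_gap_sd within-layer nearest-neighbor surface gap
#'   moments, nm.
#' @param layer_spacing_mean,layer_spacing_sd center-plane separation of
#'   fibril layers, nm.
#' @param orientation_jitter_deg per-fibril angular deviation from the common
#'   axis, degrees.
#' @param crosslink_length_mean,crosslink_length_sd cross-link
#'   surface-to-surface length moments, nm.
#' @param crosslink_density expected cross-links per fibril per 100 nm of
#'   fibril length (0 allowed).
#' @param crosslink_diameter cross-link diameter, nm. The default 3.0 nm
#'   renders bridges clearly above the detection limit set by the PSF and
#'   noise, as the measured bridges in real tomograms are.
#' @param contrast_mode "stained" (dense = bright, higher SNR typical) or
#'   "cryo" (dense = dark, low SNR).
#' @param artifact_blob_rate stain-artifact blobs per 1000 nm^3 (stained only).
#' @param middle_lamella add a dense band on one z face.
#' @param snr feature-to-background contrast over noise standard deviation.
#' @param psf_sigma isotropic Gaussian PSF sigma, nm.
#' @param missing_wedge_halfangle_deg tilt half-angle; 90 means no wedge.
#' @param tilt_scheme "single" (one tilt series: missing wedge) or "dual"
#'   (two orthogonal series, as used for resin sections: missing pyramid).
#' @param tilt_axis_azimuth_deg in-plane angle of the (first) tilt axis from
#'   the fibril (y) axis, degrees.
#' @param seed integer seed driving all generator randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(500L, 500L, 75L),
                         voxel_size = 0.87,
                         fibril_diameter_mean = 5.0,
                         fibril_diameter_sd = 1.5,
                         edge_gap_mean = 6.4,
                         edge_gap_sd = 1.2,
                         layer_spacing_mean = NULL,
                         layer_spacing_sd = 0.5,
                         orientation_jitter_deg = 2.5,
                         crosslink_length_mean = 5.0,
                         crosslink_length_sd = 1.5,
                         crosslink_density = 0.4,
                         crosslink_diameter = 3.0,
                         contrast_mode = c("stained", "cryo"),
                         artifact_blob_rate = 0.02,
                         middle_lamella = FALSE,
                         snr = 5,
                         psf_sigma = 1.0,
                         missing_wedge_halfangle_deg = 60,
                         tilt_scheme = c("single", "dual"),
                         tilt_axis_azimuth_deg = 0,
                         seed = 1L) {
  tilt_scheme <- match.arg(tilt_scheme)
  contrast_mode <- match.arg(contrast_mode)
  if (is.null(layer_spacing_mean))
    layer_spacing_mean <- 1.6 * fibril_diameter_mean + 3.0
  spec <- list(shape_voxels = as.integer(shape_voxels),
               voxel_size = voxel_size,
               fibril_diameter_mean = fibril_diameter_mean,
               fibril_diameter_sd = fibril_diameter_sd,
               edge_gap_mean = edge_gap_mean, edge_gap_sd = edge_gap_sd,
               layer_spacing_mean = layer_spacing_mean,
               layer_spacing_sd = layer_spacing_sd,
               orientation_jitter_deg = orientation_jitter_deg,
               crosslink_length_mean = crosslink_length_mean,
               crosslink_length_sd = crosslink_length_sd,
               crosslink_density = crosslink_density,
               crosslink_diameter = crosslink_diameter,
               contrast_mode = contrast_mode,
               artifact_blob_rate = artifact_blob_rate,
               middle_lamella = isTRUE(middle_lamella),
               snr = snr, psf_sigma = psf_sigma,
               missing_wedge_halfangle_deg = missing_wedge_halfangle_deg,
               tilt_scheme = tilt_scheme,
               tilt_axis_azimuth_deg = tilt_axis_azimuth_deg,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  pos <- c("voxel_size", "fibril_diameter_mean", "fibril_diameter_sd",
           "edge_gap_mean", "edge_gap_sd", "layer_spacing_mean",
           "crosslink_length_mean", "crosslink_length_sd",
           "crosslink_diameter", "snr")
  for (f in pos) {
    v <- s[[f]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) && v > 0 &&
      (is.finite(v) || f == "snr")   # snr may be Inf (noise disabled)
    if (!ok) stop("phantom_spec: ", f, " must be > 0")
  }
  if (s$psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (s$crosslink_density < 0) stop("crosslink_density must be >= 0")
  if (s$artifact_blob_rate < 0) stop("artifact_blob_rate must be >= 0")
  if (length(s$shape_voxels) != 3L || any(s$shape_voxels < 8L))
    stop("shape_voxels must be a triple >= 8")
  if (s$fibril_diameter_mean - 2 * s$fibril_diameter_sd <= 0)
    stop("fibril_diameter_mean - 2*sd must stay positive")
  w <- s$missing_wedge_halfangle_deg
  if (!(w > 0 && w <= 90))
    stop("missing_wedge_halfangle_deg must be in (0, 90]")
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> %dx%dx%d voxels @ %.3g nm, %s\n",
    "  diameter %.2f+/-%.2f nm, edge gap %.2f+/-%.2f nm,",
    " cross-link %.2f+/-%.2f nm (density %.2g)\n",
    "  snr %.3g, psf %.3g nm, wedge +/-%.0f deg, seed %d\n"),
    x$shape_voxels[1], x$shape_voxels[2], x$shape_voxels[3], x$voxel_size,
    x$contrast_mode, x$fibril_diameter_mean, x$fibril_diameter_sd,
    x$edge_gap_mean, x$edge_gap_sd, x$crosslink_length_mean,
    x$crosslink_length_sd, x$crosslink_density, x$snr, x$psf_sigma,
    x$missing_wedge_halfangle_deg, x$seed))
  invisible(x)
}

# printed measurements underlying each preset (mean, sd in nm):
# diameters / within-layer edge gaps / cross-link lengths
preset_table <- list(
  chem = list(d = c(4.3, 1.3), g = c(17.0, 4.3), l = c(5.6, 2.1),
              jitter = 6.0, mode = "stained"),
  hpf = list(d = c(4.9, 1.4), g = c(6.9, 2.1), l = c(4.6, 1.5),
             jitter = 2.5, mode = "stained"),
  cryo = list(d = c(5.0, 1.5), g = c(6.4, 1.2), l = c(5.0, 1.5),
              jitter = 2.5, mode = "cryo"),
  wt_hypocotyl = list(d = c(4.5, 0.9), g = c(5.2, 2.0), l = c(4.2, 0.8),
                      jitter = 2.5, mode = "stained"),
  cob6 = list(d = c(4.6, 0.8), g = c(8.9, 3.8), l = c(4.7, 0.8),
              jitter = 4.0, mode = "stained")
)

#' Preset phantom specifications
#'
#' Returns a fully-populated [phantom_spec] whose geometric moments are the
#' measured values for each sample-preparation condition: `chem` (chemically
#' fixed), `hpf` (high-pressure frozen / freeze substituted), `cryo`
#' (frozen-hydrated sections), `wt_hypocotyl` and `cob6` (wild-type vs mutant
#' hypocotyl parenchyma), and `extracted` (chem geometry with the cross-link
#' population removed, as after hemicellulose/pectin extraction).
#'
#' @param name preset name.
#' @param ... overrides passed on to [phantom_spec()] (e.g. `shape_voxels`,
#'   `snr`, `seed`).
#' @return a [phantom_spec].
#' @examples
#' make_preset("cryo")$fibril_diameter_mean  # 5.0 nm
#' make_preset("extracted")$crosslink_density  # 0
#' @export
make_preset <- function(name, ...) {
  valid <- c(names(preset_table), "extracted")
  if (length(name) != 1L || !name %in% valid)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  base <- if (name == "extracted") "chem" else name
  p <- preset_table[[base]]
  args <- list(shape_voxels = c(500L, 500L, 75L), voxel_size = 0.87,
               fibril_diameter_mean = p$d[1], fibril_diameter_sd = p$d[2],
               edge_gap_mean = p$g[1], edge_gap_sd = p$g[2],
               crosslink_length_mean = p$l[1], crosslink_length_sd = p$l[2],
               orientation_jitter_deg = p$jitter,
               contrast_mode = p$mode,
               snr = if (p$mode == "cryo") 3 else 5,
               artifact_blob_rate = if (p$mode == "cryo") 0 else 0.02,
               # resin sections were imaged as dual-axis series (missing
               # pyramid); the cryo sections allowed only a single-axis
               # series, with the tilt axis oblique to the fibril direction
               tilt_scheme = if (p$mode == "cryo") "single" else "dual",
               tilt_axis_azimuth_deg = if (p$mode == "cryo") 45 else 0)
  if (name == "extracted") args$crosslink_density <- 0
  user <- list(...)
  args[names(user)] <- user
  do.call(phantom_spec, args)
}

# distribution floors (nm): smallest measurements such networks show
DIAMETER_FLOOR <- 2.2
GAP_FLOOR <- 2.0
MIN_CLEARANCE <- 3.2   # smallest allowed local surface gap along y (nm):
                       # matrix polysaccharides keep microfibrils spaced,
                       # and closer approaches are unresolvable at the
                       # imaging resolution anyway

# position of a fibril axis at axial coordinate y (nm); axis = list(c0, u)
axis_at <- function(c0, u, y) {
  t <- (y - c0[2]) / u[2]
  c0 + u * t
}

#' Generate a synthetic cell-wall phantom with known geometry
#'
#' Lays near-parallel soft-edged cylindrical fibrils (axis along y) in
#' lamellae stacked along z, with per-fibril diameters, within-layer surface
#' gaps, lamella spacings and orientation jitter drawn from the spec's
#' truncated normal distributions. Cross-links are short cylinders joining
#' neighboring fibril surfaces at axial positions where the local gap admits
#' the drawn length. The returned volume is noiseless and unblurred; imaging
#' corruption is applied separately by [apply_imaging_model()]. Deterministic
#' for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [density_volume], feature level 1 on
#'   background 0) and `truth` (a `wall_ground_truth`: fibril axes/radii,
#'   cross-links, and the true neighbor-pair table).
#' @export
generate_wall_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_wall_phantom_impl(spec))
}

generate_wall_phantom_impl <- function(spec) {
  vs <- spec$voxel_size
  nx <- spec$shape_voxels[1]; ny <- spec$shape_voxels[2]
  nz <- spec$shape_voxels[3]
  Lx <- (nx - 1) * vs; Ly <- (ny - 1) * vs; Lz <- (nz - 1) * vs
  jit <- spec$orientation_jitter_deg * pi / 180

  fib <- list()   # each: c0 (z,y,x nm), u (unit), r, layer
  pair_rows <- list()
  # lamella center planes along z
  zmargin <- spec$fibril_diameter_mean / 2 + 2.5
  zc <- zmargin + if (spec$middle_lamella) 8 else 0
  layer <- 0L
  while (zc < Lz - zmargin) {
    layer <- layer + 1L
    # fibrils across x within this lamella; each new fibril must keep a
    # minimum local surface gap to its predecessor over the whole y extent
    r <- rtrunc_norm(1, spec$fibril_diameter_mean, spec$fibril_diameter_sd,
                     DIAMETER_FLOOR) / 2
    xc <- 2.0 + r
    prev <- NULL
    gap <- NA_real_
    while (xc < Lx - 2.0) {
      zjit <- stats::rnorm(1, 0, 0.4)
      c0 <- c(zc + zjit, Ly / 2, xc)
      clear <- if (is.null(prev)) 0 else
        min(MIN_CLEARANCE, max(GAP_FLOOR, 0.95 * gap))
      f <- NULL
      for (try in 1:24) {
        damp <- if (try <= 15) 1 else if (try <= 20) 0.3 else 0
        a1 <- stats::rnorm(1, 0, jit) * damp      # in-plane (x) deviation
        a2 <- stats::rnorm(1, 0, jit) * 0.2 * damp  # damped out-of-plane (z)
        u <- unit3(c(tan(a2), 1, tan(a1)))
        if (try >= 23 && !is.null(prev)) u <- prev$u  # match predecessor
        cand <- list(c0 = c0, u = u, r = r, layer = layer)
        if (is.null(prev) || pair_min_gap(prev, cand, Ly) >= clear) {
          f <- cand
          break
        }
      }
      if (!is.null(f)) {
        fib[[length(fib) + 1L]] <- f
        if (!is.null(prev)) {
          cc <- pair_closest_approach(prev, f, Ly)
          pair_rows[[length(pair_rows) + 1L]] <-
            data.frame(type = "within_layer", i = length(fib) - 1L,
                       j = length(fib),
                       center_nm = cc, edge_nm = cc - prev$r - f$r,
                       gap_mid_nm = pair_gap_profile(prev, f, Ly / 2))
        }
        prev <- f
      }
      gap <- rtrunc_norm(1, spec$edge_gap_mean, spec$edge_gap_sd, GAP_FLOOR)
      rnext <- rtrunc_norm(1, spec$fibril_diameter_mean,
                           spec$fibril_diameter_sd, DIAMETER_FLOOR) / 2
      xc <- (if (is.null(f)) xc else f$c0[3]) + (if (is.null(f)) r else f$r) +
        gap + rnext
      r <- rnext
    }
    zc <- zc + rtrunc_norm(1, spec$layer_spacing_mean, spec$layer_spacing_sd,
                           0.6 * spec$layer_spacing_mean)
  }
  if (!length(fib)) stop("geometry infeasible: no fibrils fit the volume")
  nf <- length(fib)

  # adjacent-layer nearest pairs (truth ledger only)
  layers <- vapply(fib, function(f) f$layer, integer(1))
  xs <- vapply(fib, function(f) f$c0[3], numeric(1))
  for (i in seq_len(nf)) {
    up <- which(layers == layers[i] + 1L)
    if (!length(up)) next
    j <- up[which.min(abs(xs[up] - xs[i]))]
    cc <- pair_closest_approach(fib[[i]], fib[[j]], Ly)
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(type = "adjacent_layer", i = i, j = j, center_nm = cc,
                 edge_nm = cc - fib[[i]]$r - fib[[j]]$r,
                 gap_mid_nm = pair_gap_profile(fib[[i]], fib[[j]], Ly / 2))
  }

  # cross-links: placed where a within-layer pair's local gap admits the
  # drawn surface-to-surface length (gap in [cos(50 deg) * L, L])
  cl <- place_crosslinks(spec, fib, pair_rows, Ly)

  # rasterize
  segs <- do.call(rbind, lapply(fib, function(f) {
    p0 <- axis_at(f$c0, f$u, -2)
    p1 <- axis_at(f$c0, f$u, Ly + 2)
    c(p0, p1, f$r, 1.0)
  }))
  if (nrow(cl$table) > 0) {
    cls <- cbind(as.matrix(cl$table[, c("az", "ay", "ax", "bz", "by", "bx")]),
                 spec$crosslink_diameter / 2, 1.0)
    segs <- rbind(segs, cls)
  }
  dims <- c(nz, ny, nx)
  arr <- array(0, dim = dims)
  arr <- cpp_add_capsules(as.numeric(arr), as.integer(dims), segs, vs)
  dim(arr) <- dims
  if (spec$middle_lamella) {
    nml <- max(2L, round(6 / vs))
    arr[seq_len(nml), , ] <- pmax(arr[seq_len(nml), , ], 1.2)
  }
  vol <- density_volume(arr, vs,
                        provenance = list(phantom = list(seed = spec$seed,
                                                         preset_hash = digest_spec(spec))))
  pair_tab <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(type = character(), i = integer(), j = integer(),
               center_nm = numeric(), edge_nm = numeric())
  truth <- structure(list(
    fibrils = data.frame(
      id = seq_len(nf), layer = layers,
      z = vapply(fib, function(f) f$c0[1], numeric(1)),
      y = vapply(fib, function(f) f$c0[2], numeric(1)),
      x = xs,
      uz = vapply(fib, function(f) f$u[1], numeric(1)),
      uy = vapply(fib, function(f) f$u[2], numeric(1)),
      ux = vapply(fib, function(f) f$u[3], numeric(1)),
      radius_nm = vapply(fib, function(f) f$r, numeric(1))),
    axes = lapply(fib, function(f)
      rbind(axis_at(f$c0, f$u, 0), axis_at(f$c0, f$u, Ly))),
    crosslinks = cl$table,
    true_pair_table = pair_tab,
    spec = spec), class = "wall_ground_truth")
  list(volume = vol, truth = truth)
}

digest_spec <- function(spec) {
  s <- unlist(spec[setdiff(names(spec), "shape_voxels")])
  sum(as.numeric(utf8ToInt(paste(format(s), collapse = ""))))
}

# surface gap between two near-parallel fibrils as a function of y
pair_gap_profile <- function(fi, fj, yy) {
  pi_ <- t(vapply(yy, function(y) axis_at(fi$c0, fi$u, y), numeric(3)))
  pj_ <- t(vapply(yy, function(y) axis_at(fj$c0, fj$u, y), numeric(3)))
  sqrt((pi_[, 1] - pj_[, 1])^2 + (pi_[, 3] - pj_[, 3])^2) - fi$r - fj$r
}

pair_min_gap <- function(fi, fj, Ly) {
  yy <- seq(0, Ly, by = 1)
  min(pair_gap_profile(fi, fj, yy))
}

# center-to-center distance at closest approach of the two axis lines,
# restricted to the y range of the volume
pair_closest_approach <- function(fi, fj, Ly) {
  yy <- seq(0, Ly, by = 0.25)
  g <- pair_gap_profile(fi, fj, yy)
  min(g) + fi$r + fj$r
}

place_crosslinks <- function(spec, fib, pair_rows, Ly) {
  empty <- data.frame(fibril_i = integer(), fibril_j = integer(),
                      az = numeric(), ay = numeric(), ax = numeric(),
                      bz = numeric(), by = numeric(), bx = numeric(),
                      length_nm = numeric())
  if (spec$crosslink_density <= 0 || !length(pair_rows))
    return(list(table = empty))
  wl <- Filter(function(p) p$type == "within_layer", pair_rows)
  if (!length(wl)) return(list(table = empty))
  total_len <- length(fib) * Ly
  n_target <- stats::rpois(1, spec$crosslink_density * total_len / 100)
  rows <- list()
  used_y <- lapply(seq_along(wl), function(i) numeric(0))
  yy <- seq(2, Ly - 2, by = 0.5)
  cos_lim <- cos(50 * pi / 180)
  for (k in seq_len(n_target)) {
    placed <- FALSE
    for (attempt in 1:12) {
      ell <- rtrunc_norm(1, spec$crosslink_length_mean,
                         spec$crosslink_length_sd, GAP_FLOOR)
      for (ptry in 1:30) {
        pidx <- sample.int(length(wl), 1)
        pr <- wl[[pidx]]
        fi <- fib[[pr$i]]; fj <- fib[[pr$j]]
        g <- pair_gap_profile(fi, fj, yy)
        ok <- which(g >= max(GAP_FLOOR, cos_lim * ell) & g <= ell)
        if (length(used_y[[pidx]]))
          ok <- ok[vapply(yy[ok], function(y)
            all(abs(y - used_y[[pidx]]) > 3), logical(1))]
        if (!length(ok)) next
        ystar <- yy[ok[sample.int(length(ok), 1)]]
        gstar <- g[yy == ystar][1]
        dy <- sqrt(max(ell^2 - gstar^2, 0)) * sample(c(-1, 1), 1)
        yi <- ystar - dy / 2; yj <- ystar + dy / 2
        if (yi < 1 || yi > Ly - 1 || yj < 1 || yj > Ly - 1) next
        a <- surface_point(fi, yi, axis_at(fj$c0, fj$u, yj))
        b <- surface_point(fj, yj, axis_at(fi$c0, fi$u, yi))
        len <- vec3_norm(a - b)
        rows[[length(rows) + 1L]] <- data.frame(
          fibril_i = pr$i, fibril_j = pr$j,
          az = a[1], ay = a[2], ax = a[3],
          bz = b[1], by = b[2], bx = b[3], length_nm = len)
        used_y[[pidx]] <- c(used_y[[pidx]], ystar)
        placed <- TRUE
        break
      }
      if (placed) break
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else empty)
}

# point on the surface of fibril f at axial position y, on the side facing q
surface_point <- function(f, y, q) {
  c0 <- axis_at(f$c0, f$u, y)
  w <- q - c0
  w <- w - sum(w * f$u) * f$u
  if (vec3_norm(w) < 1e-9) w <- c(1, 0, 0) - sum(c(1, 0, 0) * f$u) * f$u
  c0 + f$r * w / vec3_norm(w)
}

#' Apply the imaging model to a phantom volume
#'
#' In order: stain-artifact blobs (stained mode), isotropic Gaussian PSF,
#' missing-wedge anisotropy (the unsampled Fourier wedge - or pyramid, for
#' dual-axis acquisitions - about the beam axis is zeroed, reproducing the
#' axial elongation of tomographic reconstructions), and i.i.d. Gaussian
#' noise with standard deviation `contrast / snr`, where `contrast` is the
#' realized feature-to-background amplitude of the blurred volume (99.9th
#' percentile minus median; the nominal level 1 for featureless volumes), so
#' the delivered volume has the requested SNR. In cryo mode the volume is
#' finally negated (dense material is dark in unstained cryo data).
#'
#' @param vol a [density_volume] (noiseless phantom, feature level 1).
#' @param spec the [phantom_spec] (fields snr, psf_sigma,
#'   missing_wedge_halfangle_deg, contrast_mode, artifact_blob_rate).
#' @param seed seed for noise/blob placement; defaults to `spec$seed + 1`.
#' @return corrupted [density_volume].
#' @export
apply_imaging_model <- function(vol, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(vol, "density_volume"))
  if (!all(is.finite(vol$data))) stop("non-finite values in input volume")
  if (spec$psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (!(spec$snr > 0)) stop("snr must be > 0")
  with_seed(seed, {
    arr <- vol$data
    d <- dim(arr)
    vs <- vol$voxel_size
    if (spec$contrast_mode == "stained" && spec$artifact_blob_rate > 0) {
      volume_nm3 <- prod(d) * vs^3
      nblob <- stats::rpois(1, spec$artifact_blob_rate * volume_nm3 / 1000)
      if (nblob > 0) {
        segs <- cbind(stats::runif(nblob, 0, (d[1] - 1) * vs),
                      stats::runif(nblob, 0, (d[2] - 1) * vs),
                      stats::runif(nblob, 0, (d[3] - 1) * vs))
        segs <- cbind(segs, segs,
                      pmin(pmax(stats::rnorm(nblob, 1.5, 0.4), 0.8), 3),
                      1.2)
        arr <- cpp_add_capsules(as.numeric(arr), as.integer(d), segs, vs)
        dim(arr) <- d
      }
    }
    if (spec$psf_sigma > 0) {
      s <- spec$psf_sigma / vs
      arr <- cpp_gauss3d(as.numeric(arr), as.integer(d), rep(s, 3))
      dim(arr) <- d
    }
    if (spec$missing_wedge_halfangle_deg < 90)
      arr <- apply_missing_wedge(arr, spec$missing_wedge_halfangle_deg,
                                 spec$tilt_scheme %||% "single",
                                 spec$tilt_axis_azimuth_deg %||% 0)
    if (is.finite(spec$snr)) {
      # noise is scaled so the DELIVERED volume has the requested
      # feature-to-background contrast over noise SD: the realized feature
      # amplitude (after PSF and wedge attenuation) sets the scale; for
      # volumes without features the nominal level 1 is used
      contrast <- stats::quantile(arr, 0.999, names = FALSE) -
        stats::median(arr)
      if (!is.finite(contrast) || contrast < 0.05) contrast <- 1
      arr <- arr + stats::rnorm(length(arr), 0, contrast / spec$snr)
      dim(arr) <- d
    }
    if (spec$contrast_mode == "cryo") arr <- -arr
    out <- density_volume(arr, vs, vol$provenance)
    vol_stamp(out, "imaging",
              snr = spec$snr, psf_sigma = spec$psf_sigma,
              wedge = spec$missing_wedge_halfangle_deg,
              mode = spec$contrast_mode, seed = seed)
  })
}

# zero the unsampled Fourier region of tomographic acquisition about the
# beam (z) axis. Single-axis tilt leaves a missing wedge: k is unsampled
# when its in-plane component perpendicular to the tilt axis satisfies
# |k_perp| < tan(90 - halfangle) * |kz|. Dual-axis tilt (two orthogonal
# series) leaves only the intersection of the two wedges, a missing
# pyramid. The tilt-axis azimuth is measured in the xy-plane from the y
# axis toward x.
apply_missing_wedge <- function(arr, halfangle_deg, scheme = c("single", "dual"),
                                azimuth_deg = 0) {
  scheme <- match.arg(scheme)
  d <- dim(arr)
  kz <- array(rep(fft_freq(d[1]), times = d[2] * d[3]), dim = d)
  ky <- array(rep(rep(fft_freq(d[2]), each = d[1]), times = d[3]), dim = d)
  kx <- array(rep(fft_freq(d[3]), each = d[1] * d[2]), dim = d)
  w <- tan((90 - halfangle_deg) * pi / 180)
  phi <- azimuth_deg * pi / 180
  kp1 <- kx * cos(phi) - ky * sin(phi)   # in-plane, perpendicular to tilt axis
  miss <- abs(kp1) < w * abs(kz)
  if (scheme == "dual") {
    kp2 <- kx * sin(phi) + ky * cos(phi)
    miss <- miss & (abs(kp2) < w * abs(kz))
  }
  miss[kz == 0] <- FALSE                  # the kz = 0 plane is always sampled
  F <- stats::fft(arr)
  Re(stats::fft(F * !miss, inverse = TRUE)) / prod(d)
}

fft_freq <- function(n) {
  i <- seq_len(n) - 1
  ifelse(i <= n %/% 2, i, i - n) / n
}

#' Write ground truth tables
#'
#' Writes `fibrils.csv`, `crosslinks.csv`, `pairs.csv` and a JSON echo of the
#' generating spec into a directory.
#'
#' @param truth a `wall_ground_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "wall_ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$fibrils, file.path(dir, "fibrils.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$crosslinks, file.path(dir, "crosslinks.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$true_pair_table, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  spec <- unclass(truth$spec)
  jsonlite::write_json(spec, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Build a phantom from explicit fibril and cross-link geometry
#'
#' Fixture-oriented companion to [generate_wall_phantom()]: rasterizes the
#' given cylinders/bridges and returns the same volume + truth structure, so
#' tests can use analytically known geometry.
#'
#' @param fibrils data.frame with columns z, y, x (axis midpoint, nm),
#'   uz, uy, ux (direction), radius_nm, and optionally layer.
#' @param crosslinks optional data.frame with columns fibril_i, fibril_j, az,
#'   ay, ax, bz, by, bx (bridge endpoints, nm) and optionally radius_nm.
#' @param shape_voxels (nx, ny, nz) triple.
#' @param voxel_size nm.
#' @param crosslink_diameter nm (used when crosslinks lack radius_nm).
#' @return list with `volume` and `truth` as for [generate_wall_phantom()].
#' @export
manual_phantom <- function(fibrils, crosslinks = NULL,
                           shape_voxels = c(64L, 64L, 32L), voxel_size = 0.87,
                           crosslink_diameter = 2.0) {
  nx <- shape_voxels[1]; ny <- shape_voxels[2]; nz <- shape_voxels[3]
  Ly <- (ny - 1) * voxel_size
  if (is.null(fibrils$layer)) fibrils$layer <- 1L
  fib <- lapply(seq_len(nrow(fibrils)), function(i) {
    u <- unit3(c(fibrils$uz[i], fibrils$uy[i], fibrils$ux[i]))
    list(c0 = c(fibrils$z[i], fibrils$y[i], fibrils$x[i]), u = u,
         r = fibrils$radius_nm[i], layer = fibrils$layer[i])
  })
  segs <- do.call(rbind, lapply(fib, function(f)
    c(axis_at(f$c0, f$u, -2), axis_at(f$c0, f$u, Ly + 2), f$r, 1.0)))
  pair_rows <- list()
  for (i in seq_along(fib)) for (j in seq_along(fib)) {
    if (j <= i || fib[[i]]$layer != fib[[j]]$layer) next
    cc <- pair_closest_approach(fib[[i]], fib[[j]], Ly)
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(type = "within_layer", i = i, j = j, center_nm = cc,
                 edge_nm = cc - fib[[i]]$r - fib[[j]]$r,
                 gap_mid_nm = pair_gap_profile(fib[[i]], fib[[j]], Ly / 2))
  }
  clt <- data.frame(fibril_i = integer(), fibril_j = integer(),
                    az = numeric(), ay = numeric(), ax = numeric(),
                    bz = numeric(), by = numeric(), bx = numeric(),
                    length_nm = numeric())
  if (!is.null(crosslinks) && nrow(crosslinks)) {
    clt <- crosslinks
    clt$length_nm <- sqrt((clt$az - clt$bz)^2 + (clt$ay - clt$by)^2 +
                            (clt$ax - clt$bx)^2)
    r <- if (is.null(crosslinks$radius_nm)) crosslink_diameter / 2 else
      crosslinks$radius_nm
    segs <- rbind(segs, cbind(clt$az, clt$ay, clt$ax, clt$bz, clt$by, clt$bx,
                              r, 1.0))
  }
  dims <- c(nz, ny, nx)
  arr <- cpp_add_capsules(as.numeric(array(0, dims)), as.integer(dims), segs,
                          voxel_size)
  dim(arr) <- dims
  truth <- structure(list(
    fibrils = cbind(data.frame(id = seq_len(nrow(fibrils))), fibrils),
    axes = lapply(fib, function(f)
      rbind(axis_at(f$c0, f$u, 0), axis_at(f$c0, f$u, Ly))),
    crosslinks = clt,
    true_pair_table = if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(),
    spec = NULL), class = "wall_ground_truth")
  list(volume = density_volume(arr, voxel_size), truth = truth)
}
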