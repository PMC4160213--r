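#' Standardize a density volume for thresholding
#'
#' Maps the volume to zero mean and unit standard deviation with dense
#' features positive. Unstained cryo data render dense material dark
#' (`polarity = "dense_dark"`), so intensities are negated before
#' standardizing; stained data use `"dense_bright"`. All downstream
#' thresholds are expressed in SD units of this scale, which makes them
#' instrument-free and invariant to affine intensity rescaling of the input.
#'
#' @param vol a [density_volume].
#' @param polarity "dense_bright" or "dense_dark".
#' @return normalized [density_volume].
#' @export
normalize_density <- function(vol, polarity = c("dense_bright", "dense_dark")) {
  stopifnot(inherits(vol, "density_volume"))
  polarity <- match.arg(polarity)
  x <- vol$data
  if (polarity == "dense_dark") x <- -x
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s == 0) stop("no contrast: volume is constant")
  out <- (x - mean(x)) / s
  v <- density_volume(out, vol$voxel_size, vol$provenance)
  vol_stamp(v, "normalize", polarity = polarity)
}

#' Threshold segmentation
#'
#' Foreground = voxels strictly above `thr` (SD units on a normalized
#' volume), labeled into 26-connected components. The complementary
#' background connectivity is 6, the standard pair for consistent digital
#' topology in subsequent thinning.
#'
#' @param vol a normalized [density_volume].
#' @param thr threshold in SD units.
#' @return a `label_volume`: list with `labels` (3D integer array, 0 =
#'   background, components numbered from 1), `n_components`, `voxel_size`,
#'   `threshold`.
#' @export
threshold_segment <- function(vol, thr) {
  stopifnot(inherits(vol, "density_volume"))
  mask <- vol$data > thr
  lab <- cpp_label3d(as.integer(mask), as.integer(dim(vol$data)), 26L)
  ncomp <- attr(lab, "n_components")
  dim(lab) <- dim(vol$data)
  structure(list(labels = lab, n_components = ncomp,
                 voxel_size = vol$voxel_size, threshold = thr),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d components, %d foreground (thr %.3g)\n",
              paste(dim(x$labels), collapse = "x"), x$n_components,
              sum(x$labels > 0), x$threshold %||% NA_real_))
  invisible(x)
}

#' Contour spectrum of a volume
#'
#' Samples isovalues uniformly between the 1st and 99th intensity percentiles
#' and records, for each, the foreground (superlevel-set) volume fraction, an
#' isosurface-area proxy (count of interior voxel faces separating foreground
#' from background) and the mean gradient magnitude over boundary voxels.
#' These curves underlie automated isovalue selection.
#'
#' @param vol a [density_volume].
#' @param n_samples number of isovalues (>= 8).
#' @return data.frame with columns isovalue, volume_fraction, area,
#'   mean_gradient; class `contour_spectrum`.
#' @export
contour_spectrum <- function(vol, n_samples = 24L) {
  stopifnot(inherits(vol, "density_volume"))
  if (n_samples < 8) stop("n_samples must be >= 8")
  q <- stats::quantile(as.vector(vol$data), c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= 0) stop("degenerate intensity range")
  iso <- seq(q[1], q[2], length.out = n_samples)
  m <- cpp_contour_stats(as.numeric(vol$data), as.integer(dim(vol$data)), iso)
  structure(data.frame(isovalue = iso, volume_fraction = m[, 1],
                       area = m[, 2], mean_gradient = m[, 3]),
            class = c("contour_spectrum", "data.frame"))
}

#' Select a segmentation isovalue from a contour spectrum
#'
#' Returns the sampled isovalue maximizing the mean gradient magnitude on the
#' isosurface: the interface between background and dense features is where
#' intensity changes fastest, so the gradient-weighted criterion lands on the
#' feature boundary without operator input. Ties break toward the lower
#' isovalue. If the criterion is flat (all equal), the median sampled
#' isovalue is returned with a warning.
#'
#' @param cs a `contour_spectrum`.
#' @return selected isovalue (same units as the spectrum's volume).
#' @export
select_isovalue <- function(cs) {
  stopifnot(inherits(cs, "contour_spectrum"))
  g <- cs$mean_gradient
  if (max(g) - min(g) <= 1e-12 * max(abs(g), 1)) {
    warning("flat gradient criterion; returning median sampled isovalue")
    return(stats::median(cs$isovalue))
  }
  cs$isovalue[which.max(g)]   # which.max takes the first (lowest) maximum
}

#' Remove small components
#'
#' Deletes components below `min_voxels` voxels (noise specks) and relabels
#' the survivors contiguously from 1. The default 27 voxels corresponds to a
#' 3-voxel cube, ~2.6 nm at 0.87 nm/voxel — below the smallest real fibril
#' cross-section, so genuine features survive.
#'
#' @param labels a `label_volume`.
#' @param min_voxels minimum component size (>= 1).
#' @return cleaned `label_volume`; the number of removed components is in
#'   attribute `removed`.
#' @export
clean_components <- function(labels, min_voxels = 27L) {
  stopifnot(inherits(labels, "label_volume"))
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  if (labels$n_components == 0L || min_voxels == 1L) {
    attr(labels, "removed") <- 0L
    return(labels)
  }
  sizes <- tabulate(labels$labels[labels$labels > 0], labels$n_components)
  keep <- which(sizes >= min_voxels)
  map <- integer(labels$n_components)
  map[keep] <- seq_along(keep)
  new <- labels$labels
  pos <- new > 0
  new[pos] <- map[new[pos]]
  labels$labels <- new
  removed <- labels$n_components - length(keep)
  labels$n_components <- length(keep)
  attr(labels, "removed") <- removed
  labels
}

#' Hysteresis threshold segmentation
#'
#' Two-level segmentation: 26-connected components of the weak superlevel
#' set (`> lo`) are kept only if they contain at least one strong voxel
#' (`> hi`). This mirrors what a human operator does when thresholding by
#' visual inspection: faint stretches are kept when they continue a clearly
#' visible feature, while isolated faint blobs are rejected.
#'
#' @param vol a normalized [density_volume].
#' @param lo weak (growth) threshold, SD units.
#' @param hi strong (seed) threshold, SD units (`hi >= lo`).
#' @return a `label_volume` of the retained components.
#' @export
hysteresis_segment <- function(vol, lo, hi) {
  stopifnot(inherits(vol, "density_volume"), hi >= lo)
  d <- dim(vol$data)
  weak <- cpp_label3d(as.integer(vol$data > lo), as.integer(d), 26L)
  dim(weak) <- d
  keep <- unique(weak[vol$data > hi])
  keep <- keep[keep > 0]
  mask <- array(weak %in% keep, dim = d)
  lab <- cpp_label3d(as.integer(mask), as.integer(d), 26L)
  ncomp <- attr(lab, "n_components")
  dim(lab) <- d
  structure(list(labels = lab, n_components = ncomp,
                 voxel_size = vol$voxel_size, threshold = lo,
                 threshold_hi = hi),
            class = "label_volume")
}

# full threshold plan for the analysis pipeline: seed level, growth level
# and the half-maximum measurement level, all from background statistics
# of the filtered volume (mode, one-sided MAD) and the strong-voxel core
# level - no operator input
threshold_plan <- function(v) {
  v <- as.vector(v)
  dd <- stats::density(v, n = 512)
  bg_mode <- dd$x[which.max(dd$y)]
  med <- stats::median(v)
  s_lo <- 1.4826 * stats::median(med - v[v < med])
  if (!is.finite(s_lo) || s_lo <= 0)
    s_lo <- max(stats::sd(v) / 10, 1e-6)
  hi <- bg_mode + 2.0 * s_lo
  lo <- bg_mode + 0.8 * s_lo
  core <- stats::median(v[v > hi])
  if (!is.finite(core)) core <- max(v)
  meas <- (bg_mode + core) / 2
  meas <- min(max(meas, lo), max(hi, lo))
  list(lo = lo, hi = hi, meas = meas, bg_mode = bg_mode, s_lo = s_lo,
       core = core)
}

# operator-free stand-in for visual threshold choice: ISODATA
# (Ridler-Calvard) iteration to the midpoint between the two class means,
# guarded by a background-noise floor (mode + 2.6 robust SD) so that the
# threshold can never descend into the noise bulk, where the foreground
# would percolate into one giant component
base_threshold <- function(x) {
  v <- as.vector(x)
  t0 <- mean(v)
  for (i in 1:100) {
    lo <- v < t0
    if (all(lo) || !any(lo)) break
    t1 <- (mean(v[lo]) + mean(v[!lo])) / 2
    if (abs(t1 - t0) < 1e-6) { t0 <- t1; break }
    t0 <- t1
  }
  dd <- stats::density(v, n = 512)
  bg_mode <- dd$x[which.max(dd$y)]
  med <- stats::median(v)
  s_lo <- 1.4826 * stats::median(med - v[v < med])  # one-sided background MAD
  if (!is.finite(s_lo)) s_lo <- 0
  floor_thr <- bg_mode + 1.5 * s_lo
  max(t0, min(floor_thr, stats::quantile(v, 0.95, names = FALSE)),
      stats::quantile(v, 0.60, names = FALSE))
}

# Otsu's between-class-variance criterion on a 512-bin histogram
otsu_threshold <- function(x) {
  x <- as.vector(x)
  br <- seq(min(x), max(x), length.out = 513)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), 512)
  mids <- (br[-1] + br[-513]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[512]; mt <- m[512]
  w0 <- w[-512]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, 511)
  between[valid] <- ((mt * w0 - n * m[-512])^2 / (n^2 * w0 * w1))[valid]
  mids[which.max(between)]
}
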