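#' Density volume container
#'
#' A `density_volume` wraps a 3D numeric array of scalar density with its
#' physical voxel size. The array index order is `(z, y, x)` with the first
#' (z) axis the beam direction of the tomogram; physical coordinates in nm are
#' `0-based index * voxel_size`.
#'
#' @param data 3D numeric array, index order (z, y, x).
#' @param voxel_size isotropic voxel edge length in nm (> 0).
#' @param provenance optional named list recording origin and processing
#'   history (appended to by processing stages).
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(data, voxel_size, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  if (anyNA(data) || !all(is.finite(data)))
    stop("volume values must all be finite")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels (z,y,x), %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (length(x$provenance))
    cat(", provenance: ", paste(names(x$provenance), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

vol_stamp <- function(vol, step, ...) {
  vol$provenance[[step]] <- list(...)
  vol
}

# ---- MRC I/O ----------------------------------------------------------------
# Minimal MRC2014 reader/writer: modes 0 (int8), 1 (int16), 2 (float32).
# MRC stores the x axis fastest; internally we keep (z, y, x) with z fastest,
# so data are permuted on the way in and out. Header cell dimensions are in
# Angstrom (nm * 10).

#' Read a density volume from MRC or TIFF
#'
#' MRC modes 0/1/2 are supported, with byte order detected from the header
#' machine stamp. The voxel size is taken from the MRC cell dimensions
#' (Angstrom, converted to nm); TIFF stacks carry no physical size, so
#' `voxel_size` must be given for them.
#'
#' @param path file path (`.mrc`/`.rec` or `.tif`/`.tiff`).
#' @param voxel_size voxel size in nm; required for TIFF, overrides the header
#'   for MRC if given.
#' @return a [density_volume].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map")) {
    read_mrc(path, voxel_size)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(voxel_size))
      stop("TIFF stacks carry no voxel size; supply voxel_size (nm)")
    read_tiff_stack(path, voxel_size)
  } else {
    stop("unknown format '", ext, "'; supported: MRC (modes 0/1/2), TIFF stack")
  }
}

read_mrc <- function(path, voxel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("truncated MRC header in ", path)
  # detect endianness from the machine stamp (byte 213) or sane mode value
  endian <- "little"
  rd_int <- function(off, n = 1) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                         "integer", n = n, size = 4,
                                         endian = endian)
  rd_flt <- function(off, n = 1) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                         "numeric", n = n, size = 4,
                                         endian = endian)
  mode <- rd_int(12)
  if (mode < 0 || mode > 16) {
    endian <- "big"
    mode <- rd_int(12)
  }
  nxyz <- rd_int(0, 3)                      # nx (fast), ny, nz
  mxyz <- rd_int(28, 3)
  cella <- rd_flt(40, 3)                    # cell size in Angstrom
  if (any(nxyz <= 0)) stop("invalid MRC dimensions in ", path)
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, "; supported modes: 0, 1, 2")
  n <- prod(as.numeric(nxyz))
  what <- "integer"; size <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  if (mode == 2L) what <- "numeric"
  vals <- readBin(con, what, n = n, size = size, endian = endian,
                  signed = TRUE)
  if (length(vals) < n) stop("truncated MRC data in ", path)
  arr_xyz <- array(as.numeric(vals), dim = nxyz)      # (x, y, z), x fastest
  data <- aperm(arr_xyz, c(3, 2, 1))                  # -> (z, y, x)
  if (is.null(voxel_size)) {
    vs <- cella / pmax(mxyz, 1) / 10                  # Angstrom -> nm
    if (any(!is.finite(vs)) || any(vs <= 0))
      stop("MRC header has zero voxel size; pass voxel_size explicitly")
    if (max(vs) - min(vs) > 1e-4 * max(vs))
      warning("anisotropic MRC voxel size; using the x spacing")
    voxel_size <- vs[1]
  }
  density_volume(data, voxel_size, provenance = list(source = path))
}

#' Write a density volume
#'
#' MRC is written as mode 2 (float32) with the voxel size recorded in the
#' header cell dimensions (Angstrom = nm * 10); label volumes can be written
#' as mode 1 (int16). TIFF stacks are written as 32-bit float multi-page TIFF.
#'
#' @param vol a [density_volume] (or a 3D array plus `voxel_size`).
#' @param path output path; format chosen by extension.
#' @param mode MRC mode, 2 (float) or 1 (int16).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, mode = 2L) {
  stopifnot(inherits(vol, "density_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map")) {
    write_mrc(vol, path, mode)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_stack(vol, path)
  } else {
    stop("unknown format '", ext, "'; supported: MRC, TIFF stack")
  }
  invisible(path)
}

write_mrc <- function(vol, path, mode = 2L) {
  data <- vol$data
  d <- dim(data)                             # (z, y, x)
  arr_xyz <- aperm(data, c(3, 2, 1))         # (x, y, z), x fastest
  nxyz <- dim(arr_xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz)                                   # nx ny nz
  wi(mode)
  wi(c(0L, 0L, 0L))                          # nxstart
  wi(nxyz)                                   # mx my mz
  wf(nxyz * vol$voxel_size * 10)             # cella (Angstrom)
  wf(c(90, 90, 90))                          # cellb
  wi(c(1L, 2L, 3L))                          # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))    # dmin dmax dmean
  wi(c(0L, 0L))                              # ispg nsymbt
  writeBin(raw(100), con)                    # extra
  wf(c(0, 0, 0))                             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(data)))             # rms
  wi(0L)                                     # nlabl
  writeBin(raw(800), con)                    # labels
  if (mode == 2L) {
    wf(as.vector(arr_xyz))
  } else if (mode == 1L) {
    writeBin(as.integer(round(as.vector(arr_xyz))), con, size = 2,
             endian = "little")
  } else {
    stop("write_mrc supports modes 1 and 2")
  }
  invisible(path)
}

read_tiff_stack <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d2 <- dim(pages[[1]])
  # each page is a (row, col) = (y?, x?) matrix; we store pages as z slices
  # with page rows -> y and page cols -> x
  data <- array(0, dim = c(nz, d2[1], d2[2]))
  for (k in seq_len(nz)) data[k, , ] <- pages[[k]]
  density_volume(data, voxel_size, provenance = list(source = path))
}

write_tiff_stack <- function(vol, path) {
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) vol$data[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# ---- binning ----------------------------------------------------------------

#' Block-average downsampling
#'
#' Downsamples by block mean, multiplying the voxel size by the factor, as in
#' binning a tomogram for comparison across acquisitions. Dimensions not
#' divisible by `factor` are cropped (with a warning) before averaging.
#'
#' @param vol a [density_volume].
#' @param factor integer binning factor (>= 1).
#' @return binned [density_volume].
#' @export
bin_volume <- function(vol, factor) {
  stopifnot(inherits(vol, "density_volume"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  d <- dim(vol$data)
  if (any(factor > d)) stop("factor larger than a volume dimension")
  if (factor == 1L) return(vol)
  dnew <- d %/% factor
  if (any(d %% factor != 0L))
    warning("dimensions not divisible by factor; trailing voxels cropped")
  cropped <- vol$data[seq_len(dnew[1] * factor),
                      seq_len(dnew[2] * factor),
                      seq_len(dnew[3] * factor), drop = FALSE]
  a6 <- array(cropped, dim = c(factor, dnew[1], factor, dnew[2], factor, dnew[3]))
  out <- apply(a6, c(2, 4, 6), mean)
  v <- density_volume(out, vol$voxel_size * factor, vol$provenance)
  vol_stamp(v, "bin", factor = factor)
}
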