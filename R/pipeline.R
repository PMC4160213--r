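#' Run configuration
#'
#' Bundles everything one end-to-end run needs: the input (a preset name or
#' a volume file), the analysis configuration, ROI layout, output directory
#' and group label. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param input preset name (see [make_preset()]) or path to an MRC/TIFF
#'   volume.
#' @param voxel_size voxel size in nm (required for TIFF input).
#' @param shape_voxels phantom shape override (nx, ny, nz) for preset input.
#' @param n_rois number of ROIs the volume is split into along the fibril
#'   axis.
#' @param group group label.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param analysis a [wall_config()] list.
#' @param snr,psf_sigma,missing_wedge_halfangle_deg imaging overrides for
#'   preset input.
#' @return a `run_config` list.
#' @export
run_config <- function(input, voxel_size = NULL, shape_voxels = NULL,
                       n_rois = 3L, group = input, out_dir = "wall_out",
                       seed = 1L, analysis = wall_config(),
                       snr = NULL, psf_sigma = NULL,
                       missing_wedge_halfangle_deg = NULL) {
  structure(list(input = input, voxel_size = voxel_size,
                 shape_voxels = shape_voxels, n_rois = as.integer(n_rois),
                 group = group, out_dir = out_dir, seed = as.integer(seed),
                 analysis = analysis, snr = snr, psf_sigma = psf_sigma,
                 missing_wedge_halfangle_deg = missing_wedge_halfangle_deg),
            class = "run_config")
}

#' @export
#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
#' @rdname run_config
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_rois <- as.integer(x$n_rois)
  x$seed <- as.integer(x$seed)
  structure(x, class = "run_config")
}

preset_names <- function() c(names(preset_table), "extracted")

# resolve a run input to (volume, truth or NULL, contrast mode)
resolve_input <- function(config) {
  if (config$input %in% preset_names()) {
    args <- list(config$input, seed = config$seed)
    if (!is.null(config$shape_voxels))
      args$shape_voxels <- as.integer(config$shape_voxels)
    if (!is.null(config$snr)) args$snr <- config$snr
    if (!is.null(config$psf_sigma)) args$psf_sigma <- config$psf_sigma
    if (!is.null(config$missing_wedge_halfangle_deg))
      args$missing_wedge_halfangle_deg <- config$missing_wedge_halfangle_deg
    spec <- do.call(make_preset, args)
    ph <- generate_wall_phantom(spec)
    vol <- apply_imaging_model(ph$volume, spec)
    list(volume = vol, truth = ph$truth,
         polarity = if (spec$contrast_mode == "cryo") "dense_dark" else
           "dense_bright")
  } else {
    if (!file.exists(config$input)) stop("missing input: ", config$input)
    list(volume = read_volume(config$input, config$voxel_size), truth = NULL,
         polarity = config$analysis$polarity)
  }
}

# split a volume into n ROIs along the fibril (y) axis
split_rois <- function(vol, n, group, seed) {
  d <- dim(vol$data)
  br <- round(seq(1, d[2] + 1, length.out = n + 1))
  lapply(seq_len(n), function(i)
    analysis_roi(y = c(br[i], br[i + 1] - 1), group = group,
                 id = paste0("roi", i), seed = seed + i))
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the input volume, analyzes each ROI with
#' [analyze_roi()], pools the measurements, and writes the measurement
#' table, per-type summary, provenance JSON and resolved configuration to
#' the output directory. For phantom input a recovery report against the
#' generated ground truth is included.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `measurements`, `summary`, `truth`
#'   (NULL for file input) and `recovery` (NULL for file input).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- resolve_input(config)
  cfg <- config$analysis
  cfg$polarity <- inp$polarity
  rois <- split_rois(inp$volume, config$n_rois, config$group, config$seed)
  parts <- lapply(rois, function(r) analyze_roi(inp$volume, r, cfg))
  m <- do.call(rbind, parts)
  class(m) <- c("wall_measurements", "data.frame")
  smry <- summary(m)
  rec <- if (!is.null(inp$truth)) recovery_report(m, inp$truth) else NULL
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(m, file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(smry, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  prov <- list(config = unclass(config),
               stage_counts = lapply(parts, function(p)
                 attr(p, "provenance")$counts),
               thresholds = vapply(parts, function(p)
                 attr(p, "provenance")$threshold, numeric(1)))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  if (!is.null(rec))
    utils::write.csv(rec, file.path(config$out_dir, "recovery.csv"),
                     row.names = FALSE)
  if (!is.null(inp$truth)) write_ground_truth(inp$truth, config$out_dir)
  invisible(list(measurements = m, summary = smry, truth = inp$truth,
                 recovery = rec))
}

#' Parameter-recovery report against ground truth
#'
#' Compares the recovered per-type means with the generating truth: fibril
#' diameters against the generated fibril diameters, edge gaps against the
#' true mid-volume within-lamella gaps, cross-link lengths against the true
#' placed lengths. Pass/fail uses `max(1 voxel, rel_tol * truth mean)`.
#'
#' @param measurements a `wall_measurements` table.
#' @param truth the `wall_ground_truth` that produced the measured volume.
#' @param rel_tol relative tolerance (default 0.15).
#' @param voxel_size nm per voxel (default from the truth's spec).
#' @return data.frame with one row per measurement type present in the
#'   truth: recovered and true mean/sd, n, bias, tolerance, pass.
#' @export
recovery_report <- function(measurements, truth, rel_tol = 0.15,
                            voxel_size = NULL) {
  stopifnot(inherits(truth, "wall_ground_truth"))
  if (is.null(voxel_size))
    voxel_size <- if (!is.null(truth$spec)) truth$spec$voxel_size else 0.87
  if (nrow(measurements) == 0)
    return(data.frame(type = "none", note = "no data", pass = FALSE))
  wl <- truth$true_pair_table
  wl <- wl[wl$type == "within_layer", , drop = FALSE]
  tr <- list(
    diameter = 2 * truth$fibrils$radius_nm,
    edge_gap = if (!is.null(wl$gap_mid_nm)) wl$gap_mid_nm else wl$edge_nm,
    crosslink_len = truth$crosslinks$length_nm)
  rows <- lapply(names(tr), function(tp) {
    tv <- tr[[tp]]
    mv <- measurements$value_nm[measurements$type == tp]
    if (!length(tv))
      return(data.frame(type = tp, n_true = 0L, n_rec = length(mv),
                        true_mean = NA, rec_mean = if (length(mv)) mean(mv) else NA,
                        true_sd = NA, rec_sd = NA, bias = NA, tol = NA,
                        pass = length(mv) == 0))
    if (!length(mv))
      return(data.frame(type = tp, n_true = length(tv), n_rec = 0L,
                        true_mean = mean(tv), rec_mean = NA,
                        true_sd = stats::sd(tv), rec_sd = NA, bias = NA,
                        tol = NA, pass = FALSE))
    bias <- mean(mv) - mean(tv)
    tol <- max(voxel_size, rel_tol * mean(tv))
    data.frame(type = tp, n_true = length(tv), n_rec = length(mv),
               true_mean = mean(tv), rec_mean = mean(mv),
               true_sd = stats::sd(tv), rec_sd = stats::sd(mv),
               bias = bias, tol = tol, pass = abs(bias) <= tol)
  })
  do.call(rbind, rows)
}
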