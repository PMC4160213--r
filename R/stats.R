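#' Notched boxplot statistics
#'
#' Quartiles by linear interpolation between order statistics at positions
#' `1 + (n-1)p` (the mainstream numerics default); whiskers reach the extreme
#' data within `1.5 * IQR` of the quartiles; the notch is
#' `median +/- 1.57 * IQR / sqrt(n)`, an approximate 95% confidence interval
#' for the median.
#'
#' @param values numeric vector (nm), n >= 1.
#' @return a `wall_boxplot`: list with n, mean, median, q1, q3, iqr,
#'   whisker_low, whisker_high, notch_low, notch_high, outliers.
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty value list")
  if (anyNA(values)) stop("NA values not allowed")
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(list(
    n = n, mean = mean(values), median = q[2], q1 = q[1], q3 = q[3],
    iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    notch_low = q[2] - 1.57 * iqr / sqrt(n),
    notch_high = q[2] + 1.57 * iqr / sqrt(n),
    outliers = sort(values[values < lo_fence | values > hi_fence])),
    class = "wall_boxplot")
}

#' @export
print.wall_boxplot <- function(x, ...) {
  cat(sprintf(paste0("<wall_boxplot> n=%d median %.3g [Q1 %.3g, Q3 %.3g], ",
                     "notch (%.3g, %.3g), %d outliers\n"),
              x$n, x$median, x$q1, x$q3, x$notch_low, x$notch_high,
              length(x$outliers)))
  invisible(x)
}

#' Summary statistics in reporting style
#'
#' @param values numeric vector, n >= 1 (sample SD uses the n-1 denominator
#'   and is NA for n = 1).
#' @return list with mean, sd, min, max, n and a formatted
#'   `"mean+/-sd (min-max, n)"` report string.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty value list")
  s <- list(mean = mean(values),
            sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
            min = min(values), max = max(values), n = length(values))
  s$report <- sprintf("%.1f±%.1f nm (range %.1f–%.1f nm, n = %d)",
                      s$mean, if (is.na(s$sd)) 0 else s$sd, s$min, s$max, s$n)
  s
}

#' Two-group comparison by notch overlap
#'
#' Computes notched-boxplot statistics for both groups and declares the
#' medians significantly different exactly when the notch intervals are
#' disjoint — the standard reading of non-overlapping notches as
#' approximately non-overlapping 95% confidence intervals for the medians.
#' No additional hypothesis test is layered on.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param labels length-2 character vector naming the groups.
#' @return a `wall_comparison`: list with `stats` (two `wall_boxplot`s),
#'   `notch_overlap` (logical), `verdict` ("significant" /
#'   "not_significant"), `labels`.
#' @export
notch_overlap_test <- function(a, b, labels = c("A", "B")) {
  sa <- boxplot_stats(a)
  sb <- boxplot_stats(b)
  disjoint <- (sa$notch_high < sb$notch_low) || (sb$notch_high < sa$notch_low)
  structure(list(stats = list(sa, sb), notch_overlap = !disjoint,
                 verdict = if (disjoint) "significant" else "not_significant",
                 labels = labels),
            class = "wall_comparison")
}

#' @export
print.wall_comparison <- function(x, ...) {
  cat(sprintf("<wall_comparison> %s vs %s: medians %.3g vs %.3g -> %s\n",
              x$labels[1], x$labels[2], x$stats[[1]]$median,
              x$stats[[2]]$median, x$verdict))
  invisible(x)
}

#' Notched boxplot figure for a group comparison
#'
#' Renders the comparison in the conventional layout: median band, box,
#' 1.5*IQR whiskers, notches, mean diamonds and outlier circles, drawn from
#' the exact statistics in the object.
#'
#' @param x a `wall_comparison`.
#' @param ylab y axis label.
#' @param ... passed to [graphics::bxp()].
#' @return invisibly, the bxp group positions.
#' @export
plot.wall_comparison <- function(x, ylab = "nm", ...) {
  st <- vapply(x$stats, function(s)
    c(s$whisker_low, s$q1, s$median, s$q3, s$whisker_high), numeric(5))
  conf <- vapply(x$stats, function(s) c(s$notch_low, s$notch_high), numeric(2))
  z <- list(stats = st, n = vapply(x$stats, function(s) s$n, numeric(1)),
            conf = conf,
            out = unlist(lapply(x$stats, function(s) s$outliers)),
            group = rep(seq_along(x$stats),
                        vapply(x$stats, function(s) length(s$outliers),
                               integer(1))),
            names = x$labels)
  pos <- graphics::bxp(z, notch = TRUE, ylab = ylab, ...)
  graphics::points(seq_along(x$stats),
                   vapply(x$stats, function(s) s$mean, numeric(1)),
                   pch = 18, cex = 1.4)
  invisible(pos)
}

#' Threshold sensitivity sweep
#'
#' Re-runs [analyze_roi()] with the segmentation threshold offset by each
#' `delta` (SD units) and reports, per offset, the mean diameter, mean edge
#' gap and mean cross-link length plus their shifts relative to delta = 0 —
#' the robustness check for operator threshold choice.
#'
#' @param vol a [density_volume].
#' @param roi an [analysis_roi()].
#' @param config base [wall_config()] (its `delta` is replaced per run).
#' @param deltas offsets in SD units; must include 0.
#' @return data.frame with one row per delta: n/mean per measurement type and
#'   shift columns; rows with empty segmentations are flagged in `empty`.
#' @export
threshold_sensitivity <- function(vol, roi = analysis_roi(),
                                  config = wall_config(),
                                  deltas = c(-0.15, -0.05, 0, 0.05, 0.15)) {
  if (!any(deltas == 0)) stop("deltas must include 0")
  rows <- lapply(deltas, function(dl) {
    cfg <- config
    cfg$delta <- dl
    m <- tryCatch(analyze_roi(vol, roi, cfg), error = function(e) NULL)
    mt <- function(tp) {
      if (is.null(m)) return(c(NA_real_, 0))
      v <- m$value_nm[m$type == tp]
      c(if (length(v)) mean(v) else NA_real_, length(v))
    }
    di <- mt("diameter"); ge <- mt("edge_gap"); cl <- mt("crosslink_len")
    data.frame(delta = dl, empty = is.null(m) || di[2] == 0,
               mean_diameter_nm = di[1], n_diameter = di[2],
               mean_edge_gap_nm = ge[1], n_edge_gap = ge[2],
               mean_crosslink_nm = cl[1], n_crosslink = cl[2])
  })
  out <- do.call(rbind, rows)
  base <- out[out$delta == 0, ]
  out$diameter_shift_nm <- out$mean_diameter_nm - base$mean_diameter_nm
  out$edge_gap_shift_nm <- out$mean_edge_gap_nm - base$mean_edge_gap_nm
  out$crosslink_shift_nm <- out$mean_crosslink_nm - base$mean_crosslink_nm
  out
}
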