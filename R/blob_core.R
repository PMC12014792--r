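#' Mean echointensity within the ROI
#'
#' The echointensity of a frame is the arithmetic mean of its 0-255 grayscale
#' values over the included ROI pixels.
#'
#' @param frame an [ultrasound_frame()].
#' @param roi a congruent [roi_mask()].
#' @return A number in `[0, 255]`.
#' @export
compute_echointensity <- function(frame, roi) {
  stopifnot(inherits(frame, "ultrasound_frame"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), dim(frame$pixels)))
    stop("ROI mask not congruent with frame")
  mean(frame$pixels[roi$mask])
}

#' Percentile reference thresholds from a healthy cohort
#'
#' Pools the grayscale values of every ROI pixel across all frames of the
#' supplied healthy scans and takes the stated percentiles of the pooled
#' distribution. Percentiles use linear interpolation between order statistics
#' (R quantile type 7), recorded in the result so downstream reports are
#' auditable. Blob metrics are then computed relative to these thresholds, so
#' brightness is always referenced to the healthy distribution.
#'
#' @param healthy_scans list of [subject_scan()] (or a single scan); typically
#'   the healthy arm of a cohort. Mixed lists of `list(frame=, mask=)` pairs
#'   are accepted too.
#' @param percentiles numeric vector of percentile levels in `(0, 100)`,
#'   strictly increasing; default `c(95, 99)`.
#' @param min_pixels minimum pooled pixel count (floor 100).
#' @return An object of class `threshold_set`: list with `thresholds` (named
#'   `p95`, `p99`, ...), `percentiles`, `source_n_pixels`, `definition`.
#' @export
reference_thresholds <- function(healthy_scans, percentiles = c(95, 99),
                                 min_pixels = 100L) {
  if (inherits(healthy_scans, "subject_scan"))
    healthy_scans <- list(healthy_scans)
  if (!length(healthy_scans)) stop("no healthy subjects supplied")
  if (any(percentiles <= 0) || any(percentiles >= 100) ||
      is.unsorted(percentiles, strictly = TRUE))
    stop("percentiles must be strictly increasing and inside (0, 100)")
  pool <- unlist(lapply(healthy_scans, function(s) {
    frames <- if (inherits(s, "subject_scan")) s$frames else list(s)
    lapply(frames, function(fr) fr$frame$pixels[fr$mask$mask])
  }), use.names = FALSE)
  if (length(pool) < max(100L, min_pixels))
    stop(sprintf("pooled healthy ROI pixel count %d below floor %d",
                 length(pool), max(100L, min_pixels)))
  th <- stats::quantile(pool, percentiles / 100, type = 7, names = FALSE)
  names(th) <- paste0("p", format(percentiles, trim = TRUE))
  structure(
    list(thresholds = th, percentiles = percentiles,
         source_n_pixels = length(pool),
         definition = "linear interpolation between order statistics (type 7)"),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set: %s from %d pooled healthy ROI pixels>\n",
              paste(sprintf("%s=%.2f", names(x$thresholds), x$thresholds),
                    collapse = ", "),
              x$source_n_pixels))
  invisible(x)
}

#' Binarize a frame against a grayscale threshold
#'
#' A pixel maps to 1 iff it is inside the ROI and its grayscale value is at or
#' above the threshold; everything else (including all pixels outside the ROI)
#' maps to 0. Ties at the threshold are counted as bright.
#'
#' @param frame an [ultrasound_frame()].
#' @param roi a congruent [roi_mask()].
#' @param threshold grayscale cutoff in `[0, 255]` (fractional values from
#'   interpolated percentiles are allowed).
#' @return Integer 0/1 matrix of the frame's dimensions.
#' @export
binarize <- function(frame, roi, threshold) {
  stopifnot(inherits(frame, "ultrasound_frame"), inherits(roi, "roi_mask"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single value in [0, 255]")
  out <- matrix(0L, nrow(frame$pixels), ncol(frame$pixels))
  out[roi$mask & frame$pixels >= threshold] <- 1L
  out
}

#' Label blobs (connected bright regions) in a binary map
#'
#' Partitions the 1-pixels into maximal connected components under 4- or
#' 8-neighbor adjacency (compiled two-pass union-find). Components are labeled
#' 1..N in raster (row-major) order of their first pixel.
#'
#' @param binary integer/logical binary matrix (e.g. from [binarize()]).
#' @param connectivity 4 or 8 (default 8, the usual choice for bright-region
#'   blob analysis).
#' @param pixel_area_mm2 optional pixel area; when given, `size_mm2` is added.
#' @param min_size_px drop blobs smaller than this many pixels (default 1,
#'   i.e. no filtering).
#' @return A data.frame with one row per blob: `label`, `size_px`,
#'   `centroid_row`, `centroid_col` (0-based), and `size_mm2` when
#'   `pixel_area_mm2` is given. The label matrix is attached as
#'   `attr(, "labels")`.
#' @export
label_blobs <- function(binary, connectivity = 8, pixel_area_mm2 = NULL,
                        min_size_px = 1L) {
  if (is.logical(binary)) { storage.mode(binary) <- "integer" }
  if (!is.matrix(binary) || !is.numeric(binary))
    stop("binary must be a 0/1 matrix")
  storage.mode(binary) <- "integer"
  lab <- cc_label(binary, as.integer(connectivity))
  st <- cc_stats(lab)
  out <- data.frame(label = seq_along(st$size_px),
                    size_px = st$size_px,
                    centroid_row = st$centroid_row,
                    centroid_col = st$centroid_col)
  if (!is.null(pixel_area_mm2))
    out$size_mm2 <- out$size_px * pixel_area_mm2
  if (min_size_px > 1L) out <- out[out$size_px >= min_size_px, , drop = FALSE]
  attr(out, "labels") <- lab
  out
}

#' Band map between two thresholds
#'
#' Exploration aid: marks ROI pixels whose grayscale lies in
#' `[lower, upper)` — e.g. between the 95th and 99th percentile thresholds.
#'
#' @inheritParams binarize
#' @param lower,upper grayscale bounds, `lower <= upper`.
#' @return Integer 0/1 matrix.
#' @export
band_map <- function(frame, roi, lower, upper) {
  stopifnot(lower <= upper)
  out <- matrix(0L, nrow(frame$pixels), ncol(frame$pixels))
  out[roi$mask & frame$pixels >= lower & frame$pixels < upper] <- 1L
  out
}

#' Blob metrics for one frame
#'
#' Computes, independently at each percentile threshold level: blob count,
#' total blob size (pixels and mm2), and the per-mm2 normalizations (count and
#' total pixel size divided by the ROI area in mm2), plus the frame
#' echointensity and ROI area. Column names follow the
#' `<metric>_p<level>` convention (e.g. `blob_count_p95`).
#'
#' @param frame an [ultrasound_frame()].
#' @param roi a congruent [roi_mask()].
#' @param thresholds a `threshold_set` from [reference_thresholds()].
#' @param connectivity 4 or 8 (default 8).
#' @param min_blob_px minimum blob size in pixels (default 1 = keep all).
#' @return One-row data.frame.
#' @export
frame_report <- function(frame, roi, thresholds, connectivity = 8,
                         min_blob_px = 1L) {
  stopifnot(inherits(thresholds, "threshold_set"))
  px_area <- frame$spacing_axial * frame$spacing_lateral
  out <- data.frame(frame_id = frame$frame_id,
                    echointensity = compute_echointensity(frame, roi),
                    roi_n_pixels = roi$n_pixels,
                    roi_area_mm2 = roi$area_mm2)
  for (k in seq_along(thresholds$thresholds)) {
    suffix <- paste0("_", names(thresholds$thresholds)[k])
    blobs <- label_blobs(binarize(frame, roi, thresholds$thresholds[k]),
                         connectivity = connectivity,
                         pixel_area_mm2 = px_area,
                         min_size_px = min_blob_px)
    total_px <- sum(blobs$size_px)
    vals <- c(blob_count = nrow(blobs),
              total_blob_size_px = total_px,
              total_blob_size_mm2 = total_px * px_area,
              blob_count_per_mm2 = nrow(blobs) / roi$area_mm2,
              total_blob_size_per_mm2 = total_px / roi$area_mm2)
    out[paste0(names(vals), suffix)] <- as.list(unname(vals))
  }
  out
}

#' Blob metrics for one subject (mean over the three frames)
#'
#' Aggregates [frame_report()] across the subject's three frames; the default
#' is the arithmetic mean, with the median available.
#'
#' @param scan a [subject_scan()].
#' @inheritParams frame_report
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return One-row data.frame with `subject_id`, `group`, and the aggregated
#'   metrics (same column names as [frame_report()]).
#' @export
subject_report <- function(scan, thresholds, connectivity = 8,
                           aggregate = c("mean", "median"), min_blob_px = 1L) {
  stopifnot(inherits(scan, "subject_scan"))
  aggregate <- match.arg(aggregate)
  reps <- do.call(rbind, lapply(scan$frames, function(fr)
    frame_report(fr$frame, fr$mask, thresholds, connectivity, min_blob_px)))
  num <- reps[, setdiff(names(reps), "frame_id"), drop = FALSE]
  agg <- if (aggregate == "mean") colMeans(num) else apply(num, 2, stats::median)
  cbind(data.frame(subject_id = scan$subject_id, group = scan$group),
        as.data.frame(as.list(agg)))
}

#' Blob metrics for a whole cohort
#'
#' One row per subject: group, subject-level blob metrics, and (optionally)
#' joined clinical covariates.
#'
#' @param scans list of [subject_scan()].
#' @inheritParams subject_report
#' @param covariates optional data.frame keyed by `subject_id` (as produced by
#'   [load_cohort()] or [simulate_cohort()]); joined by subject. Subjects with
#'   no covariate row trigger an error naming them.
#' @return data.frame (a "cohort table") with one row per subject.
#' @export
cohort_metrics <- function(scans, thresholds, connectivity = 8,
                           covariates = NULL,
                           aggregate = c("mean", "median"), min_blob_px = 1L) {
  if (!length(scans)) stop("empty cohort")
  aggregate <- match.arg(aggregate)
  tab <- do.call(rbind, lapply(scans, subject_report, thresholds = thresholds,
                               connectivity = connectivity,
                               aggregate = aggregate,
                               min_blob_px = min_blob_px))
  rownames(tab) <- NULL
  if (!is.null(covariates)) {
    missing <- setdiff(tab$subject_id, covariates$subject_id)
    if (length(missing))
      stop(sprintf("no covariates for subject(s): %s",
                   paste(missing, collapse = ", ")))
    cov <- covariates[, setdiff(names(covariates), "group"), drop = FALSE]
    tab <- merge(tab, cov, by = "subject_id", sort = FALSE)
  }
  tab
}
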