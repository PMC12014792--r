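#' Construct an ultrasound frame
#'
#' An `ultrasound_frame` is an 8-bit grayscale B-mode image (0 = darkest,
#' 255 = brightest) together with its physical pixel spacing. Row 0 (R index 1)
#' is the shallowest tissue; coordinates are (row, col) throughout.
#'
#' @param pixels integer matrix of grayscale values in `[0, 255]`.
#' @param spacing_axial mm per pixel row (depth direction); must be `> 0`.
#' @param spacing_lateral mm per pixel column; must be `> 0`.
#' @param frame_id identifier carried through reports.
#' @return An object of class `ultrasound_frame` with elements `pixels`,
#'   `spacing_axial`, `spacing_lateral`, `frame_id`.
#' @examples
#' f <- ultrasound_frame(matrix(100L, 8, 8), 0.4, 0.4, "demo")
#' @export
ultrasound_frame <- function(pixels, spacing_axial, spacing_lateral,
                             frame_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels)))
      stop("pixels must be integer grayscale values")
    storage.mode(pixels) <- "integer"
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixels must lie in [0, 255] with no missing values")
  if (!is.numeric(spacing_axial) || length(spacing_axial) != 1L ||
      is.na(spacing_axial) || spacing_axial <= 0)
    stop("spacing_axial must be a single positive number (mm/pixel)")
  if (!is.numeric(spacing_lateral) || length(spacing_lateral) != 1L ||
      is.na(spacing_lateral) || spacing_lateral <= 0)
    stop("spacing_lateral must be a single positive number (mm/pixel)")
  structure(
    list(pixels = pixels,
         spacing_axial = as.numeric(spacing_axial),
         spacing_lateral = as.numeric(spacing_lateral),
         frame_id = as.character(frame_id)),
    class = "ultrasound_frame"
  )
}

#' @export
print.ultrasound_frame <- function(x, ...) {
  cat(sprintf("<ultrasound_frame '%s': %d x %d px, %.3g x %.3g mm/px, gray %d-%d>\n",
              x$frame_id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_axial, x$spacing_lateral,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' A binary inclusion mask congruent with its frame, delineating the muscle
#' area (fascia and other tissue excluded). The physical ROI area is
#' `n_pixels * spacing_axial * spacing_lateral`.
#'
#' @param mask logical (or 0/1) matrix with the same dimensions as the frame;
#'   `TRUE`/nonzero = included. Must include at least one pixel.
#' @param frame the [ultrasound_frame()] the mask belongs to.
#' @return An object of class `roi_mask` with elements `mask` (logical),
#'   `n_pixels`, `area_mm2`.
#' @export
roi_mask <- function(mask, frame) {
  stopifnot(inherits(frame, "ultrasound_frame"))
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!identical(dim(mask), dim(frame$pixels)))
    stop(sprintf("mask dimensions (%d x %d) do not match frame (%d x %d)",
                 nrow(mask), ncol(mask), nrow(frame$pixels), ncol(frame$pixels)))
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical or numeric 0/1")
  if (anyNA(mask)) stop("mask must not contain missing values")
  n <- sum(mask)
  if (n < 1L) stop("empty ROI: mask includes no pixels")
  structure(
    list(mask = mask,
         n_pixels = as.integer(n),
         area_mm2 = n * frame$spacing_axial * frame$spacing_lateral),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask: %d px, %.2f mm2>\n", x$n_pixels, x$area_mm2))
  invisible(x)
}

#' Construct a subject scan (three frames plus masks)
#'
#' Subjects are scanned with three consecutive static B-mode frames; blob
#' metrics are aggregated across the three.
#'
#' @param subject_id subject identifier (unique within a cohort).
#' @param group `"healthy"` or `"fm"`.
#' @param frames list of exactly 3 elements, each `list(frame = , mask = )`
#'   with an [ultrasound_frame()] and congruent [roi_mask()]. All frames must
#'   share one pixel spacing.
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, group, frames) {
  group <- match.arg(group, c("healthy", "fm"))
  if (!is.list(frames) || length(frames) != 3L)
    stop(sprintf("subject '%s': exactly 3 frames required, got %d",
                 subject_id, length(frames)))
  for (fr in frames) {
    if (!is.list(fr) || !inherits(fr$frame, "ultrasound_frame") ||
        !inherits(fr$mask, "roi_mask"))
      stop(sprintf("subject '%s': each frame entry needs $frame and $mask",
                   subject_id))
  }
  sp <- vapply(frames, function(fr)
    c(fr$frame$spacing_axial, fr$frame$spacing_lateral), numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-12))
    stop(sprintf("subject '%s': frames do not share one pixel spacing",
                 subject_id))
  structure(
    list(subject_id = as.character(subject_id), group = group, frames = frames),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan '%s' (%s): 3 frames>\n", x$subject_id, x$group))
  invisible(x)
}
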