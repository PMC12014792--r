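#' Read an 8-bit grayscale PNG frame
#'
#' Thresholds in this pipeline are defined on the 0-255 grayscale, so inputs
#' that are not 8-bit are rejected rather than silently rescaled. Multi-channel
#' images are accepted only when all channels are identical (gray stored as
#' RGB); an alpha channel, if present and fully opaque, is dropped.
#'
#' @param path path to a single-channel 8-bit PNG.
#' @param spacing_axial,spacing_lateral pixel spacing in mm (required; frames
#'   carry no spacing metadata of their own).
#' @param frame_id identifier; defaults to the file name.
#' @return An [ultrasound_frame()].
#' @export
read_frame <- function(path, spacing_axial, spacing_lateral,
                       frame_id = basename(path)) {
  v <- read_gray_png(path)
  ultrasound_frame(v, spacing_axial, spacing_lateral, frame_id = frame_id)
}

# shared PNG -> integer matrix reader used for frames and masks
read_gray_png <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop(sprintf("'%s': only 8-bit PNG is supported (no TIFF/DICOM reader available)",
                 path))
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop(sprintf("unreadable file '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 4L) {
      if (any(img[, , 4] < 1)) stop(sprintf("'%s': transparent pixels present", path))
      img <- img[, , 1:3, drop = FALSE]
      nc <- 3L
    }
    if (nc >= 2L) {
      for (k in 2:nc) if (any(img[, , k] != img[, , 1]))
        stop(sprintf("'%s': multi-channel image without unambiguous grayscale conversion",
                     path))
      img <- img[, , 1]
    } else img <- img[, , 1]
  }
  v <- img * 255
  if (any(abs(v - round(v)) > 1e-6))
    stop(sprintf("'%s': bit depth not 8; rescale explicitly", path))
  matrix(as.integer(round(v)), nrow(img), ncol(img))
}

#' Write a frame as an 8-bit grayscale PNG
#'
#' Inverse of [read_frame()]: `read_frame(write_frame(f, p), ...)` reproduces
#' the pixel matrix exactly.
#'
#' @param frame an [ultrasound_frame()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "ultrasound_frame"))
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' Read a binary ROI mask PNG
#'
#' Mask images are single-channel PNGs parallel to their frame: 0 = excluded,
#' any nonzero = included. At most two distinct pixel values are allowed, and
#' the mask must include at least one pixel.
#'
#' @param path path to the mask PNG.
#' @param frame the [ultrasound_frame()] the mask delineates.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, frame) {
  v <- read_gray_png(path)
  if (!identical(dim(v), dim(frame$pixels)))
    stop(sprintf("'%s': mask dimensions (%d x %d) do not match frame (%d x %d)",
                 path, nrow(v), ncol(v), nrow(frame$pixels), ncol(frame$pixels)))
  u <- unique(as.vector(v))
  if (length(u) > 2L)
    stop(sprintf("'%s': mask has %d distinct values; expected a binary image",
                 path, length(u)))
  if (all(u == 0L)) stop(sprintf("'%s': empty ROI", path))
  roi_mask(v != 0L, frame)
}

#' Write an ROI mask as a binary PNG (0 / 255)
#' @param mask an [roi_mask()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(ifelse(mask$mask, 1, 0), path)
  invisible(path)
}

manifest_required_cols <- c("subject_id", "group",
                            paste0("frame", 1:3), paste0("mask", 1:3),
                            "spacing_axial_mm", "spacing_lateral_mm")

#' Load a cohort from a CSV manifest
#'
#' The manifest has one row per subject with columns `subject_id`, `group`
#' (`healthy`/`fm`), `frame1..frame3`, `mask1..mask3`, `spacing_axial_mm`,
#' `spacing_lateral_mm`, followed by any number of clinical covariate columns.
#' File paths are resolved relative to the manifest's directory unless
#' absolute. Covariates may be missing (`NA`) for group-specific instruments
#' (e.g. WPI/SSS/FIQ in healthy controls).
#'
#' @param manifest_path path to the manifest CSV.
#' @return A list with `scans` (list of [subject_scan()], in manifest order
#'   keyed by `subject_id`) and `covariates` (data.frame keyed by
#'   `subject_id`, including `group`).
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: '%s'", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(manifest_required_cols, names(man))
  if (length(missing_cols))
    stop(sprintf("manifest '%s' missing column(s): %s",
                 manifest_path, paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(man$subject_id))
    stop(sprintf("duplicate subject_id in manifest: %s",
                 paste(unique(man$subject_id[duplicated(man$subject_id)]),
                       collapse = ", ")))
  bad_group <- !man$group %in% c("healthy", "fm")
  if (any(bad_group))
    stop(sprintf("invalid group for subject(s): %s",
                 paste(man$subject_id[bad_group], collapse = ", ")))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))

  scans <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    fpaths <- unlist(row[paste0("frame", 1:3)], use.names = FALSE)
    mpaths <- unlist(row[paste0("mask", 1:3)], use.names = FALSE)
    if (anyNA(fpaths) || anyNA(mpaths) || any(!nzchar(c(fpaths, mpaths))))
      stop(sprintf("subject '%s' (row %d): 3 frames and 3 masks required",
                   row$subject_id, i))
    fpaths <- resolve(fpaths); mpaths <- resolve(mpaths)
    gone <- c(fpaths, mpaths)[!file.exists(c(fpaths, mpaths))]
    if (length(gone))
      stop(sprintf("subject '%s' (row %d): missing file(s): %s",
                   row$subject_id, i, paste(gone, collapse = ", ")))
    frames <- lapply(1:3, function(k) {
      fr <- read_frame(fpaths[k], row$spacing_axial_mm, row$spacing_lateral_mm,
                       frame_id = sprintf("%s_f%d", row$subject_id, k))
      list(frame = fr, mask = read_mask(mpaths[k], fr))
    })
    scans[[i]] <- subject_scan(row$subject_id, row$group, frames)
  }
  names(scans) <- man$subject_id
  cov_cols <- setdiff(names(man), setdiff(manifest_required_cols,
                                          c("subject_id", "group")))
  covariates <- man[, cov_cols, drop = FALSE]
  list(scans = scans, covariates = covariates)
}
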