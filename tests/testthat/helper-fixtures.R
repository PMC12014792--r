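# Shared fixtures and independent oracles (kept free of package internals).

# constant-value frame with full-field ROI
const_frame <- function(value = 100L, nr = 6, nc = 8, spacing = c(0.4, 0.4)) {
  f <- ultrasound_frame(matrix(as.integer(value), nr, nc),
                        spacing[1], spacing[2], frame_id = "const")
  list(frame = f, mask = roi_mask(matrix(TRUE, nr, nc), f))
}

# frame with arbitrary pixel matrix and full ROI
pix_frame <- function(pixels, spacing = c(1, 1)) {
  f <- ultrasound_frame(pixels, spacing[1], spacing[2], frame_id = "pix")
  list(frame = f, mask = roi_mask(matrix(TRUE, nrow(pixels), ncol(pixels)), f))
}

# subject with three frames drawn from a pixel-matrix factory
scan_of <- function(id, group, make_pixels, spacing = c(0.4, 0.4)) {
  subject_scan(id, group, lapply(1:3, function(k) pix_frame(make_pixels(k),
                                                            spacing)))
}

# independent connected-component oracle: stack-based flood fill, labels
# assigned in row-major discovery order (same canonical order as label_blobs)
flood_fill_labels <- function(bin, connectivity) {
  nr <- nrow(bin); nc <- ncol(bin)
  offs <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (bin[r, cc] == 0 || lab[r, cc] != 0) next
    cur <- cur + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            bin[rr, c2] != 0 && lab[rr, c2] == 0) {
          lab[rr, c2] <- cur
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# small, fast generator preset for pipeline-level tests
small_preset <- function() {
  p <- reference_preset()
  p$frame_rows <- 96L
  p$frame_cols <- 64L
  p
}
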