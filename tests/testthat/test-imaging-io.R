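test_that("frame construction enforces the 8-bit data model", {
  expect_error(ultrasound_frame(matrix(300L, 2, 2), 0.4, 0.4), "0, 255")
  expect_error(ultrasound_frame(matrix(-1L, 2, 2), 0.4, 0.4), "0, 255")
  expect_error(ultrasound_frame(matrix(1.5, 2, 2), 0.4, 0.4), "integer")
  expect_error(ultrasound_frame(matrix(1L, 0, 0), 0.4, 0.4), "non-empty")
  expect_error(ultrasound_frame(matrix(1L, 2, 2), 0, 0.4), "positive")
  f <- ultrasound_frame(matrix(0:3, 2, 2), 0.5, 0.3, "x")
  expect_identical(f$pixels, matrix(0:3, 2, 2))
})

test_that("PNG frames round-trip bit-identically and reject non-8-bit input", {
  withr::local_dir(withr::local_tempdir())
  # constant-value identity case
  cf <- const_frame(100L, 12, 10)
  write_frame(cf$frame, "const.png")
  back <- read_frame("const.png", 0.4, 0.4)
  expect_true(all(back$pixels == 100L))
  # synthetic frame round-trip
  fr <- simulate_frame(reference_preset()$healthy, size = c(64, 64),
                       seed = 7, compression_gain = 85,
                       psf_sigma_px = c(1.8, 4))$frame
  write_frame(fr, "synth.png")
  expect_identical(read_frame("synth.png", 0.4, 0.4)$pixels, fr$pixels)
  # 16-bit grayscale PNG (written via PIL) is rejected, not rescaled
  ok <- system2("python", c("-c", shQuote(paste0(
    "from PIL import Image; import numpy as np; ",
    "Image.fromarray((np.arange(64, dtype=np.uint16).reshape(8, 8) * 700), ",
    "mode='I;16').save('deep.png')"))), stdout = FALSE, stderr = FALSE)
  if (ok == 0L)
    expect_error(read_frame("deep.png", 0.4, 0.4), "bit depth not 8")
  # RGB with unequal channels has no unambiguous grayscale conversion
  png::writePNG(array(c(rep(0.5, 8), rep(0.2, 4)), dim = c(2, 2, 3)), "rgb.png")
  expect_error(read_frame("rgb.png", 0.4, 0.4), "multi-channel")
  # but gray-as-RGB (all channels equal) is accepted
  png::writePNG(array(rep(100 / 255, 12), dim = c(2, 2, 3)), "gray3.png")
  expect_true(all(read_frame("gray3.png", 0.4, 0.4)$pixels == 100L))
  expect_error(read_frame("nope.png", 0.4, 0.4), "not found")
  expect_error(read_frame("frame.tif", 0.4, 0.4), "PNG")
})

test_that("masks validate dimensions, binarity, emptiness, and area arithmetic", {
  withr::local_dir(withr::local_tempdir())
  cf <- const_frame(100L, 58, 25, spacing = c(0.4, 0.4))
  # full mask: every pixel included
  png::writePNG(matrix(1, 58, 25), "full.png")
  m <- read_mask("full.png", cf$frame)
  expect_identical(m$n_pixels, 58L * 25L)
  # 1000 pixels at 0.4 x 0.4 mm -> 160 mm2
  big <- const_frame(100L, 50, 40, spacing = c(0.4, 0.4))
  mm <- matrix(0, 50, 40); mm[1:25, 1:40] <- 1
  png::writePNG(mm, "part.png")
  expect_equal(read_mask("part.png", big$frame)$area_mm2, 160)
  # empty and malformed masks
  png::writePNG(matrix(0, 58, 25), "empty.png")
  expect_error(read_mask("empty.png", cf$frame), "empty ROI")
  png::writePNG(matrix(c(0, 0.5, 1, 1), 2, 2), "tri.png")
  small <- const_frame(10L, 2, 2)
  expect_error(read_mask("tri.png", small$frame), "distinct values")
  png::writePNG(matrix(1, 10, 10), "dim.png")
  expect_error(read_mask("dim.png", cf$frame), "dimensions")
})

test_that("load_cohort builds scans, joins covariates, and reports bad rows", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(3, seed = 11, preset = small_preset(), dir = dir)
  cohort <- load_cohort(sim$manifest)
  expect_length(cohort$scans, 6)
  expect_identical(sum(vapply(cohort$scans, function(s) s$group == "fm",
                              logical(1))), 3L)
  # loaded pixels match the in-memory originals exactly
  expect_identical(cohort$scans[["F01"]]$frames[[2]]$frame$pixels,
                   sim$scans[["F01"]]$frames[[2]]$frame$pixels)
  expect_true(all(c("pain_vas", "csi_total", "bmi") %in%
                    names(cohort$covariates)))

  man <- read.csv(sim$manifest, check.names = FALSE)
  # order-insensitive: shuffling rows yields the same cohort keyed by id
  shuf <- man[rev(seq_len(nrow(man))), ]
  p2 <- file.path(dir, "shuffled.csv")
  write.csv(shuf, p2, row.names = FALSE)
  c2 <- load_cohort(p2)
  expect_setequal(names(c2$scans), names(cohort$scans))
  expect_identical(c2$scans[["H02"]]$frames[[1]]$frame$pixels,
                   cohort$scans[["H02"]]$frames[[1]]$frame$pixels)

  # frame count != 3 reported with the subject id
  bad <- man; bad$frame3[2] <- NA
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "bad.csv")), man$subject_id[2])
  # duplicate subject id
  dup <- rbind(man, man[1, ])
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "dup.csv")), "duplicate")
  # missing column
  write.csv(man[, -3], file.path(dir, "miss.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "miss.csv")), "missing column")
  # missing file
  gone <- man; gone$mask1[1] <- "images/nowhere.png"
  write.csv(gone, file.path(dir, "gone.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "gone.csv")), "missing file")
})
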