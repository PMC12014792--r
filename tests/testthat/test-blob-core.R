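test_that("echointensity is the ROI mean on the 0-255 scale", {
  cf <- const_frame(100L)
  expect_identical(compute_echointensity(cf$frame, cf$mask), 100)
  pf <- pix_frame(matrix(c(0L, 255L, 100L, 45L), 2, 2))
  expect_identical(compute_echointensity(pf$frame, pf$mask), 100)
  # partial ROI: only included pixels count
  f <- ultrasound_frame(matrix(c(10L, 10L, 200L, 200L), 2, 2), 1, 1)
  m <- roi_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), f)
  expect_identical(compute_echointensity(f, m), 10)
})

test_that("reference thresholds follow the interpolated-percentile definition", {
  # pooled values exactly 1..100 (repeated across frames) -> type-7 interpolation
  sc <- scan_of("h1", "healthy",
                function(k) matrix(as.integer(rep(1:100, 2)), 10, 20))
  th <- reference_thresholds(list(sc), percentiles = c(95, 99))
  expect_equal(unname(th$thresholds), c(95.05, 99.01), tolerance = 1e-10)
  expect_identical(th$source_n_pixels, 600L)

  # degenerate distribution: all pixels equal c -> t95 = t99 = c
  sc2 <- scan_of("h2", "healthy", function(k) matrix(42L, 10, 20))
  th2 <- reference_thresholds(list(sc2))
  expect_equal(unname(th2$thresholds), c(42, 42))

  # pooling is invariant to how pixels are split across subjects/frames
  scA <- scan_of("a", "healthy", function(k) matrix(as.integer(k * 10), 10, 10))
  scB <- scan_of("b", "healthy", function(k) matrix(as.integer(100 + k), 10, 10))
  expect_equal(reference_thresholds(list(scA, scB))$thresholds,
               reference_thresholds(list(scB, scA))$thresholds)

  expect_error(reference_thresholds(list()), "no healthy")
  tiny <- scan_of("t", "healthy", function(k) matrix(1L, 2, 2))
  expect_error(reference_thresholds(list(tiny)), "below floor")
  expect_error(reference_thresholds(list(sc), percentiles = c(99, 95)),
               "strictly increasing")
})

test_that("binarize uses >= inside the ROI and zero outside", {
  pf <- pix_frame(matrix(c(10L, 200L, 200L, 10L), 2, 2))
  expect_identical(binarize(pf$frame, pf$mask, 100),
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))
  # threshold 0: binary map equals the ROI mask
  f <- ultrasound_frame(matrix(0:24, 5, 5), 1, 1)
  m <- roi_mask(matrix(rep(c(TRUE, FALSE), length.out = 25), 5, 5), f)
  expect_identical(binarize(f, m, 0), matrix(as.integer(m$mask), 5, 5))
  # above the maximum: all zeros
  expect_true(all(binarize(f, m, 255) == 0L))
  expect_error(binarize(f, m, 300), "0, 255")
  # ties at the threshold count as bright
  tf <- pix_frame(matrix(c(99L, 100L, 101L, 0L), 2, 2))
  expect_identical(sum(binarize(tf$frame, tf$mask, 100)), 2L)
})

test_that("label_blobs matches the flood-fill oracle on random matrices", {
  set.seed(401)
  for (i in 1:60) {
    bin <- matrix(rbinom(400, 1, runif(1, 0.2, 0.7)), 20, 20)
    for (conn in c(4, 8)) {
      blobs <- label_blobs(bin, connectivity = conn)
      expect_identical(attr(blobs, "labels"), flood_fill_labels(bin, conn),
                       label = sprintf("iter %d conn %d", i, conn))
      # conservation: blob sizes partition the foreground
      expect_identical(sum(blobs$size_px), sum(bin))
    }
  }
})

test_that("label_blobs handles empty, full, and known geometries", {
  expect_identical(nrow(label_blobs(matrix(0L, 5, 5))), 0L)
  full <- label_blobs(matrix(1L, 4, 6))
  expect_identical(full$size_px, 24L)
  # two diagonal pixels: one blob at 8-connectivity, two at 4
  d <- matrix(0L, 3, 3); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_identical(nrow(label_blobs(d, 8)), 1L)
  expect_identical(nrow(label_blobs(d, 4)), 2L)
  # centroid and mm2 bookkeeping
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  b <- label_blobs(sq, 8, pixel_area_mm2 = 0.16)
  expect_equal(b$size_mm2, 9 * 0.16)
  expect_equal(c(b$centroid_row, b$centroid_col), c(2, 2)) # 0-based center
  expect_error(label_blobs(sq, connectivity = 6), "connectivity")
})

test_that("frame_report computes the full metric set at both levels", {
  # one 3x3 bright square on a dark ROI, t95 = 200 -> one blob of 9 px
  px <- matrix(10L, 12, 12); px[4:6, 5:7] <- 255L
  pf <- pix_frame(px, spacing = c(0.5, 0.5))
  th <- structure(list(thresholds = c(p95 = 200, p99 = 250),
                       percentiles = c(95, 99), source_n_pixels = 1000L,
                       definition = "fixed"), class = "threshold_set")
  rep <- frame_report(pf$frame, pf$mask, th)
  expect_equal(rep$blob_count_p95, 1)
  expect_equal(rep$total_blob_size_px_p95, 9)
  expect_equal(rep$total_blob_size_mm2_p95, 9 * 0.25)
  expect_equal(rep$roi_area_mm2, 144 * 0.25)
  expect_equal(rep$blob_count_per_mm2_p95, 1 / 36)
  expect_equal(rep$total_blob_size_per_mm2_p95, 9 / 36)
  # unit spacing: per-mm2 metrics equal pixel metrics / n_pixels
  pf1 <- pix_frame(px, spacing = c(1, 1))
  r1 <- frame_report(pf1$frame, pf1$mask, th)
  expect_equal(r1$blob_count_per_mm2_p95, r1$blob_count_p95 / 144)
  expect_equal(r1$total_blob_size_per_mm2_p95,
               r1$total_blob_size_px_p95 / 144)
})

test_that("threshold monotonicity and spacing equivariance hold on speckle", {
  fr <- simulate_frame(reference_preset()$healthy, size = c(96, 64), seed = 5,
                       compression_gain = 85, psf_sigma_px = c(1.8, 4))
  pool <- fr$frame$pixels[fr$mask$mask]
  th <- structure(list(thresholds = c(p95 = quantile(pool, .95, names = FALSE),
                                      p99 = quantile(pool, .99, names = FALSE)),
                       percentiles = c(95, 99), source_n_pixels = length(pool),
                       definition = "type 7"), class = "threshold_set")
  rep <- frame_report(fr$frame, fr$mask, th)
  expect_lte(rep$total_blob_size_px_p99, rep$total_blob_size_px_p95)
  expect_lte(rep$total_blob_size_px_p95, fr$mask$n_pixels)

  # doubling both spacings quadruples areas, divides per-mm2 metrics by 4
  f2 <- ultrasound_frame(fr$frame$pixels, fr$frame$spacing_axial * 2,
                         fr$frame$spacing_lateral * 2)
  m2 <- roi_mask(fr$mask$mask, f2)
  rep2 <- frame_report(f2, m2, th)
  expect_equal(rep2$roi_area_mm2, 4 * rep$roi_area_mm2)
  expect_identical(rep2$total_blob_size_px_p95, rep$total_blob_size_px_p95)
  expect_equal(rep2$blob_count_per_mm2_p95, rep$blob_count_per_mm2_p95 / 4)
  expect_equal(rep2$total_blob_size_per_mm2_p95,
               rep$total_blob_size_per_mm2_p95 / 4)
})

test_that("subject_report averages frames and is order-invariant", {
  th <- structure(list(thresholds = c(p95 = 100, p99 = 200),
                       percentiles = c(95, 99), source_n_pixels = 1000L,
                       definition = "fixed"), class = "threshold_set")
  # frames with 2, 4, 6 isolated bright pixels -> mean blob count 4
  mk <- function(k) {
    px <- matrix(0L, 10, 10)
    px[cbind(seq(1, 2 * 2 * k, by = 2) %% 10 + 1,
             (seq_len(2 * k) * 3) %% 10 + 1)] <- 255L
    px
  }
  counts <- integer(3)
  sc <- scan_of("s1", "fm", mk)
  for (k in 1:3) counts[k] <- frame_report(sc$frames[[k]]$frame,
                                           sc$frames[[k]]$mask, th)$blob_count_p95
  rep <- subject_report(sc, th)
  expect_equal(rep$blob_count_p95, mean(counts))
  # identical frames -> subject metrics equal frame metrics
  sc_id <- scan_of("s2", "fm", function(k) mk(2))
  rep_id <- subject_report(sc_id, th)
  fr_rep <- frame_report(sc_id$frames[[1]]$frame, sc_id$frames[[1]]$mask, th)
  expect_equal(rep_id$echointensity, fr_rep$echointensity)
  expect_equal(rep_id$blob_count_p95, as.numeric(fr_rep$blob_count_p95))
  # permuting frames leaves the report unchanged
  sc_perm <- subject_scan("s1", "fm", sc$frames[c(3, 1, 2)])
  expect_equal(subject_report(sc_perm, th)[, -1],
               rep[, -1])
})

test_that("cohort_metrics joins covariates and is deterministic", {
  sim1 <- simulate_cohort(3, seed = 99, preset = small_preset())
  sim2 <- simulate_cohort(3, seed = 99, preset = small_preset())
  healthy <- Filter(function(s) s$group == "healthy", sim1$scans)
  th <- reference_thresholds(healthy)
  m1 <- cohort_metrics(sim1$scans, th, covariates = sim1$covariates)
  m2 <- cohort_metrics(sim2$scans, th, covariates = sim2$covariates)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 6L)
  expect_false(anyNA(m1$total_blob_size_px_p95))
  expect_true(all(c("csi_total", "pain_vas") %in% names(m1)))
  # healthy-only cohort is usable as its own threshold source
  mh <- cohort_metrics(healthy, reference_thresholds(healthy))
  expect_identical(nrow(mh), 3L)
  # covariate join failure names the subject
  cov_bad <- sim1$covariates[-2, ]
  expect_error(cohort_metrics(sim1$scans, th, covariates = cov_bad),
               sim1$covariates$subject_id[2])
})
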