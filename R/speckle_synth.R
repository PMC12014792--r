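# Synthetic B-mode speckle cohorts: Rayleigh amplitude -> (optional PSF blur)
# -> multiplicative hyperechoic inclusions -> log compression to 0-255.

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic substream seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Group-level parameters of the speckle generator
#'
#' @param mean_echointensity_target target mean grayscale of the group (the
#'   tuned `speckle_scale` realizes it; kept for documentation/auditing).
#' @param speckle_scale Rayleigh scale of the pre-compression amplitude field.
#' @param inclusion_rate expected hyperechoic fibrous bands per cm2 of ROI.
#' @param inclusion_length_mm,inclusion_width_mm mean inclusion geometry;
#'   width must be smaller than length (fiber-aligned anisotropy).
#' @param inclusion_brightness_gain multiplicative amplitude boost at the
#'   inclusion core (> 1).
#' @param between_subject_sd SD of the per-subject random effect on the log
#'   amplitude scale (multiplies `speckle_scale` by `exp(effect)`).
#' @return list of class `group_params`.
#' @export
group_params <- function(mean_echointensity_target, speckle_scale,
                         inclusion_rate, inclusion_length_mm = 4,
                         inclusion_width_mm = 1,
                         inclusion_brightness_gain = 2,
                         between_subject_sd = 0.03) {
  vals <- c(mean_echointensity_target, speckle_scale, inclusion_length_mm,
            inclusion_width_mm, inclusion_brightness_gain, between_subject_sd)
  if (any(!is.finite(vals)) || any(vals <= 0) ||
      !is.finite(inclusion_rate) || inclusion_rate < 0)
    stop("group_params: all parameters must be positive (inclusion_rate >= 0)")
  if (inclusion_width_mm >= inclusion_length_mm)
    stop("inclusion_width_mm must be < inclusion_length_mm")
  structure(list(mean_echointensity_target = mean_echointensity_target,
                 speckle_scale = speckle_scale,
                 inclusion_rate = inclusion_rate,
                 inclusion_length_mm = inclusion_length_mm,
                 inclusion_width_mm = inclusion_width_mm,
                 inclusion_brightness_gain = inclusion_brightness_gain,
                 between_subject_sd = between_subject_sd),
            class = "group_params")
}

#' Latent-severity covariate model
#'
#' Each FM subject carries a latent severity `z ~ N(0, 1)`. Every symptom
#' score is `mean + loading * z + noise`, truncated to its instrument range;
#' loadings on symptom scores are positive so severity and symptoms correlate
#' positively. Quality-of-life (SF-36) subscales load negatively. Severity is
#' cross-linked to the imaging generator: it multiplies the inclusion rate by
#' `exp(severity_rate_link * z)` and shifts the subject log-amplitude effect
#' by `severity_echo_link * z`, so blob metrics carry a recoverable
#' correlation with pain/CSI.
#'
#' @param scores named list; each element is
#'   `c(mean, load, sd, min, max, digits)` for the FM group.
#' @param healthy named list with the same structure for healthy controls
#'   (loadings ignored; healthy have no latent severity).
#' @param severity_rate_link,severity_echo_link cross-link coefficients.
#' @return list of class `covariate_model`.
#' @export
covariate_model <- function(scores = NULL, healthy = NULL,
                            severity_rate_link = 0.6,
                            severity_echo_link = 0.03) {
  sc <- function(mean, load, sd, min, max, digits = 1)
    c(mean = mean, load = load, sd = sd, min = min, max = max, digits = digits)
  if (is.null(scores)) scores <- list(
    # FM medians/ranges guide the means; instrument ranges enforced
    pain_vas      = sc(7.3,  1.0, 0.9,  0, 10),
    fatigue_vas   = sc(7.6,  0.9, 0.9,  0, 10),
    sleep_vas     = sc(5.8,  1.1, 1.3,  0, 10),
    csi_total     = sc(50,  12.0, 10.6, 0, 100, 0),
    bdi           = sc(18,   6.0, 6.7,  0, 63, 0),
    bai           = sc(20,   8.0, 8.0,  0, 63, 0),
    fiq           = sc(65,  10.0, 9.0,  0, 100, 1),
    wpi           = sc(15,   2.2, 2.0,  6, 19, 0),
    sss           = sc(9.5,  1.7, 1.5,  2, 13, 0),
    sf36_physical_functioning = sc(50, -15, 18, 0, 100, 0),
    sf36_physical_role        = sc(25, -20, 30, 0, 100, 0),
    sf36_bodily_pain          = sc(35, -12, 16, 0, 100, 0),
    sf36_general_health       = sc(30, -10, 14, 0, 100, 0),
    sf36_vitality             = sc(30, -12, 15, 0, 100, 0),
    sf36_social_functioning   = sc(50, -14, 18, 0, 100, 0),
    sf36_emotional_role       = sc(25, -20, 32, 0, 100, 0),
    sf36_mental_health        = sc(45, -12, 14, 0, 100, 0)
  )
  if (is.null(healthy)) healthy <- list(
    pain_vas      = sc(1.5, 0, 1.1, 0, 10),
    fatigue_vas   = sc(2.5, 0, 1.4, 0, 10),
    sleep_vas     = sc(2.0, 0, 1.4, 0, 10),
    csi_total     = sc(25,  0, 10,  0, 100, 0),
    bdi           = sc(7,   0, 4,   0, 63, 0),
    bai           = sc(9,   0, 5,   0, 63, 0),
    sf36_physical_functioning = sc(92, 0, 8,  0, 100, 0),
    sf36_physical_role        = sc(85, 0, 22, 0, 100, 0),
    sf36_bodily_pain          = sc(75, 0, 16, 0, 100, 0),
    sf36_general_health       = sc(68, 0, 14, 0, 100, 0),
    sf36_vitality             = sc(56, 0, 13, 0, 100, 0),
    sf36_social_functioning   = sc(76, 0, 16, 0, 100, 0),
    sf36_emotional_role       = sc(85, 0, 24, 0, 100, 0),
    sf36_mental_health        = sc(65, 0, 12, 0, 100, 0)
  )
  structure(list(scores = scores, healthy = healthy,
                 severity_rate_link = severity_rate_link,
                 severity_echo_link = severity_echo_link),
            class = "covariate_model")
}

#' The frozen reference preset
#'
#' Generator parameters tuned once (see `tools/tune_preset.R`) so that, at the
#' default 256 x 128 frame size and 0.4 mm isotropic spacing, a 34 + 34 cohort
#' approximates the reference study's group statistics: healthy mean
#' echointensity ~72 gray levels, pooled-healthy 95th-percentile tail by
#' construction (total blob size ~5% of ROI pixels), FM/healthy total-blob-size
#' ratio ~1.45 with group CVs ~0.23 (healthy) and ~0.31 (FM), and a moderate
#' positive blob-size/CSI correlation. Pixel-count metrics scale with ROI
#' area, so absolute counts match the study after scaling by relative ROI size.
#'
#' @return list with `healthy` and `fm` [group_params()], `covmodel`
#'   ([covariate_model()]), and frame-level settings (`frame_rows`,
#'   `frame_cols`, `spacing`, `compression_gain`, `psf_sigma_px`,
#'   `roi_margin_frac`, `frame_jitter_sd`).
#' @export
reference_preset <- function() {
  list(
    healthy = group_params(mean_echointensity_target = 71.95,
                           speckle_scale = 1.154,
                           inclusion_rate = 0.24,
                           between_subject_sd = 0.0343),
    fm      = group_params(mean_echointensity_target = 78.48,
                           speckle_scale = 1.154 * 1.043,
                           inclusion_rate = 0.85,
                           between_subject_sd = 0.0343),
    covmodel = covariate_model(severity_rate_link = 0.4,
                               severity_echo_link = 0.030),
    frame_rows = 256L, frame_cols = 128L,
    spacing = c(0.4, 0.4),
    compression_gain = 85,
    psf_sigma_px = c(1.8, 4.0),   # axial, lateral: fiber-aligned speckle grain
    roi_margin_frac = 0.08,
    frame_jitter_sd = 0.01
  )
}

# row-normalized separable Gaussian smoothing matrix
blur_band <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-0.5 * (d / sigma)^2)
  k[d > 3 * sigma] <- 0
  k / rowSums(k)
}

# Fully developed speckle: blur the complex scatterer field with a separable
# Gaussian PSF and take the envelope. The per-pixel variance is renormalized,
# so the marginal amplitude stays exactly Rayleigh(scale) at any PSF size —
# blurring sets the speckle grain (spatial correlation), not the contrast.
speckle_field <- function(nr, nc, scale, psf_sigma_px) {
  re <- matrix(stats::rnorm(nr * nc), nr, nc)
  im <- matrix(stats::rnorm(nr * nc), nr, nc)
  varfac <- 1
  if (any(psf_sigma_px > 0)) {
    Br <- if (psf_sigma_px[1] > 0) blur_band(nr, psf_sigma_px[1]) else diag(nr)
    Bc <- if (psf_sigma_px[2] > 0) blur_band(nc, psf_sigma_px[2]) else diag(nc)
    re <- Br %*% re %*% t(Bc)
    im <- Br %*% im %*% t(Bc)
    varfac <- outer(rowSums(Br^2), rowSums(Bc^2))
  }
  scale * sqrt((re^2 + im^2) / varfac)
}

# multiply elongated Gaussian-profile ellipses into an amplitude field
apply_inclusions <- function(A, roi_rows, spacing, rate_per_cm2, length_mm,
                             width_mm, gain, angle_sd = 0.05) {
  nr <- nrow(A); nc <- ncol(A)
  area_cm2 <- length(roi_rows) * nc * spacing[1] * spacing[2] / 100
  n_inc <- stats::rpois(1, rate_per_cm2 * area_cm2)
  if (n_inc == 0) return(A)
  for (i in seq_len(n_inc)) {
    cy <- stats::runif(1, min(roi_rows), max(roi_rows))
    cx <- stats::runif(1, 1, nc)
    a_mm <- (length_mm / 2) * stats::rlnorm(1, 0, 0.3)  # lateral half-axis
    b_mm <- (width_mm / 2) * stats::rlnorm(1, 0, 0.3)   # axial half-axis
    th <- stats::rnorm(1, 0, angle_sd)                  # near-lateral alignment
    ext_r <- ceiling(2.2 * max(a_mm * abs(sin(th)) + b_mm, b_mm) / spacing[1])
    ext_c <- ceiling(2.2 * (a_mm + b_mm) / spacing[2])
    rr <- max(1, floor(cy - ext_r)):min(nr, ceiling(cy + ext_r))
    cc <- max(1, floor(cx - ext_c)):min(nc, ceiling(cx + ext_c))
    dy <- (rr - cy) * spacing[1]
    dx <- (cc - cx) * spacing[2]
    # rotated elliptical squared distance, lateral = major axis
    DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
    DY <- matrix(dy, length(rr), length(cc))
    u <- (DX * cos(th) + DY * sin(th)) / a_mm
    v <- (-DX * sin(th) + DY * cos(th)) / b_mm
    A[rr, cc] <- A[rr, cc] * (1 + (gain - 1) * exp(-(u^2 + v^2)))
  }
  A
}

#' Simulate one synthetic B-mode frame and its ROI mask
#'
#' Pipeline: Rayleigh speckle amplitude field (envelope of a complex Gaussian
#' scatterer field; an optional separable Gaussian PSF sets the speckle grain
#' without changing the Rayleigh marginal), Poisson-placed laterally-aligned
#' elliptical inclusions multiplying the amplitude, logarithmic compression
#' `gain * log(1 + A)` mapped to 0-255, clip and round. The ROI is a
#' horizontal band excluding top and bottom margins (a fascia stand-in).
#'
#' @param params a [group_params()].
#' @param subject_effect per-subject random effect on the log amplitude scale.
#' @param size `c(rows, cols)`, each >= 64.
#' @param spacing `c(axial_mm, lateral_mm)` per pixel.
#' @param seed integer seed (required: frames are reproducible by contract).
#' @param frame_id identifier.
#' @param compression_gain log-compression gain (gray levels per log unit).
#' @param psf_sigma_px `c(axial, lateral)` Gaussian PSF sigmas in pixels;
#'   `c(0, 0)` disables blurring.
#' @param roi_margin_frac fraction of rows excluded at top and bottom.
#' @param inclusion_rate_mult multiplier on `params$inclusion_rate` (used for
#'   the severity cross-link).
#' @return `list(frame = , mask = )` with an [ultrasound_frame()] and
#'   [roi_mask()].
#' @export
simulate_frame <- function(params, subject_effect = 0, size = c(256L, 128L),
                           spacing = c(0.4, 0.4), seed, frame_id = "synthetic",
                           compression_gain = 50, psf_sigma_px = c(0, 0),
                           roi_margin_frac = 0.08, inclusion_rate_mult = 1) {
  stopifnot(inherits(params, "group_params"))
  if (length(size) != 2L || any(size < 64))
    stop("size must be c(rows, cols) with both >= 64")
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  margin <- max(4L, round(roi_margin_frac * nr))
  roi_rows <- (margin + 1L):(nr - margin)
  pixels <- with_seed(seed, {
    A <- speckle_field(nr, nc, params$speckle_scale * exp(subject_effect),
                       psf_sigma_px)
    if (params$inclusion_rate * inclusion_rate_mult > 0)
      A <- apply_inclusions(A, roi_rows, spacing,
                            params$inclusion_rate * inclusion_rate_mult,
                            params$inclusion_length_mm,
                            params$inclusion_width_mm,
                            params$inclusion_brightness_gain)
    matrix(as.integer(pmin(255, pmax(0, round(compression_gain * log1p(A))))),
           nr, nc)
  })
  frame <- ultrasound_frame(pixels, spacing[1], spacing[2], frame_id = frame_id)
  m <- matrix(FALSE, nr, nc)
  m[roi_rows, ] <- TRUE
  list(frame = frame, mask = roi_mask(m, frame))
}

# draw one subject's covariates; z is the latent severity (0 for healthy)
draw_covariates <- function(group, z, covmodel) {
  defs <- if (group == "fm") covmodel$scores else covmodel$healthy
  out <- lapply(defs, function(d) {
    val <- d["mean"] + (if (group == "fm") d["load"] * z else 0) +
      stats::rnorm(1, 0, d["sd"])
    round(min(max(val, d["min"]), d["max"]), d["digits"])
  })
  names(out) <- names(defs)
  # anthropometrics: shared distributions, weight derived from BMI and height
  age <- round(min(max(stats::rnorm(1, if (group == "fm") 45 else 39, 8), 18), 60))
  bmi <- round(min(max(stats::rnorm(1, if (group == "fm") 28.2 else 25.8, 3.5),
                       17), 42), 2)
  height <- stats::rnorm(1, 1.62, 0.06)
  extra <- list(age = age, bmi = bmi, weight = round(bmi * height^2, 1))
  if (group == "fm") {
    extra$complaint_months <- round(min(max(exp(log(72) + 0.5 * z +
                                                  stats::rnorm(1, 0, 0.8)), 1), 360))
    extra$diagnosis_months <- round(min(max(exp(log(24) + 0.4 * z +
                                                  stats::rnorm(1, 0, 0.9)), 1), 240))
    extra$drug_class <- sample(c("none", "duloxetine", "duloxetine_pregabalin",
                                 "pregabalin", "amitriptyline"), 1,
                               prob = c(19, 8, 3, 3, 1) / 34)
    extra$ipaq_category <- sample(c("inactive", "low", "sufficient"), 1,
                                  prob = c(9, 23, 2) / 34)
    extra$ipaq_total <- round(exp(stats::rnorm(1, log(3600), 0.9)))
  } else {
    extra$complaint_months <- NA_real_
    extra$diagnosis_months <- NA_real_
    extra$drug_class <- "none"
    extra$ipaq_category <- sample(c("inactive", "low", "sufficient"), 1,
                                  prob = c(22, 11, 1) / 34)
    extra$ipaq_total <- round(exp(stats::rnorm(1, log(2600), 0.9)))
    out$wpi <- NA_real_; out$sss <- NA_real_; out$fiq <- NA_real_
  }
  c(extra, out)
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_per_group` healthy and `n_per_group` FM subjects, three frames
#' each, with clinical covariates from the latent-severity model. One master
#' seed expands into per-subject and per-frame substreams, so cohorts are
#' reproducible and extendable.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param seed master integer seed.
#' @param preset generator preset; see [reference_preset()].
#' @param dir optional output directory: when given, frames and masks are
#'   written as PNG files and a `manifest.csv` consumable by [load_cohort()]
#'   is created; when `NULL` (default) the cohort is returned in memory.
#' @return list with `scans` (list of [subject_scan()]), `covariates`
#'   (data.frame), and — when `dir` is given — `manifest` (path to the CSV).
#' @export
simulate_cohort <- function(n_per_group = 34, seed = 1,
                            preset = reference_preset(), dir = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  n <- 2L * n_per_group
  groups <- rep(c("healthy", "fm"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "healthy", "H", "F"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  subj_seeds <- derive_seeds(seed, n)
  size <- c(preset$frame_rows, preset$frame_cols)

  scans <- vector("list", n)
  cov_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    params <- preset[[g]]
    sub <- with_seed(subj_seeds[i], {
      z <- if (g == "fm") stats::rnorm(1) else 0
      list(z = z,
           effect = stats::rnorm(1, 0, params$between_subject_sd) +
             preset$covmodel$severity_echo_link * z,
           covs = draw_covariates(g, z, preset$covmodel),
           frame_seeds = sample.int(.Machine$integer.max - 1L, 3L),
           jitter = stats::rnorm(3, 0, preset$frame_jitter_sd))
    })
    rate_mult <- exp(preset$covmodel$severity_rate_link * sub$z)
    frames <- lapply(1:3, function(k)
      simulate_frame(params,
                     subject_effect = sub$effect + sub$jitter[k],
                     size = size, spacing = preset$spacing,
                     seed = sub$frame_seeds[k],
                     frame_id = sprintf("%s_f%d", ids[i], k),
                     compression_gain = preset$compression_gain,
                     psf_sigma_px = preset$psf_sigma_px,
                     roi_margin_frac = preset$roi_margin_frac,
                     inclusion_rate_mult = rate_mult))
    scans[[i]] <- subject_scan(ids[i], g, frames)
    cov_rows[[i]] <- data.frame(subject_id = ids[i], group = g,
                                latent_severity = sub$z,
                                sub$covs, stringsAsFactors = FALSE)
  }
  names(scans) <- ids
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  out <- list(scans = scans, covariates = covariates)

  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop(sprintf("cannot create output directory '%s'", dir))
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    man <- covariates[, c("subject_id", "group")]
    for (k in 1:3) {
      man[[paste0("frame", k)]] <- file.path("images",
                                             sprintf("%s_f%d.png", ids, k))
      man[[paste0("mask", k)]] <- file.path("images",
                                            sprintf("%s_m%d.png", ids, k))
    }
    man$spacing_axial_mm <- preset$spacing[1]
    man$spacing_lateral_mm <- preset$spacing[2]
    man <- cbind(man, covariates[, setdiff(names(covariates),
                                           c("subject_id", "group")),
                                 drop = FALSE])
    for (i in seq_len(n)) for (k in 1:3) {
      fr <- scans[[i]]$frames[[k]]
      write_frame(fr$frame, file.path(dir, man[[paste0("frame", k)]][i]))
      write_mask(fr$mask, file.path(dir, man[[paste0("mask", k)]][i]))
    }
    manifest_path <- file.path(dir, "manifest.csv")
    utils::write.csv(man, manifest_path, row.names = FALSE)
    out$manifest <- manifest_path
  }
  out
}

#' Simulate a covariate-only cohort with a known regression structure
#'
#' Generates subject-level rows (no images) where the blob-density response is
#' constructed linearly from pain VAS and diagnosis duration with known slopes
#' plus Gaussian noise, alongside pure-nuisance predictors. Used to verify
#' that [backward_ols()] recovers the generating slope.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param slope_pain true slope of `total_blob_size_per_mm2` on `pain_vas`.
#' @param slope_dxdur true slope on `diagnosis_months`.
#' @param noise_sd residual SD of the response.
#' @return data.frame with `pain_vas`, `diagnosis_months`, `age`, `bmi`,
#'   `sleep_vas` (nuisance) and `total_blob_size_per_mm2`; true slopes are
#'   attached as attributes `slope_pain`, `slope_dxdur`.
#' @export
simulate_regression_cohort <- function(n = 500, seed = 1,
                                       slope_pain = 83.706,
                                       slope_dxdur = -3.255,
                                       noise_sd = 120) {
  with_seed(seed, {
    z <- stats::rnorm(n)
    pain <- pmin(pmax(7.3 + 1.0 * z + stats::rnorm(n, 0, 0.9), 0), 10)
    dxdur <- pmin(pmax(exp(log(24) + 0.4 * z + stats::rnorm(n, 0, 0.9)), 1), 240)
    d <- data.frame(
      pain_vas = pain,
      diagnosis_months = dxdur,
      age = round(pmin(pmax(stats::rnorm(n, 45, 8), 18), 60)),
      bmi = pmin(pmax(stats::rnorm(n, 28.2, 3.5), 17), 42),
      sleep_vas = pmin(pmax(5.8 + stats::rnorm(n, 0, 1.6), 0), 10)
    )
    d$total_blob_size_per_mm2 <- 1000 + slope_pain * d$pain_vas +
      slope_dxdur * d$diagnosis_months + stats::rnorm(n, 0, noise_sd)
    attr(d, "slope_pain") <- slope_pain
    attr(d, "slope_dxdur") <- slope_dxdur
    d
  })
}
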