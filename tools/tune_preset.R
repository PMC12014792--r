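#!/usr/bin/env Rscript
# One-time calibration of the frozen reference preset (see reference_preset()).
#
# Targets, taken from the reference study's printed group statistics and
# rescaled to the generator's 256 x 128 frames (pixel-count metrics scale with
# ROI area; the pooled-healthy 95th-percentile construction pins the healthy
# mean total blob size at ~5% of ROI pixels):
#   healthy mean echointensity  71.95
#   healthy total blob size     CV 0.2325  (printed 1680.21 +/- 390.59)
#   FM / healthy blob-size ratio 1.4509    (printed 2437.68 / 1680.21)
#   FM total blob size          CV 0.3079  (printed 750.61 / 2437.68)
#   moderate positive blob-size ~ CSI correlation in the FM group
# The printed echointensity SDs (~11.4) and the blob-size CVs are jointly
# unattainable under a percentile-tail model (a 11-gray-level between-subject
# SD makes the 5% tail vary with CV >> 1); the preset prioritizes the
# blob-size distributions, so the generated echo SD is a few gray levels.
#
# Run from the repository root:  Rscript tools/tune_preset.R
# Prints the tuned constants; they are frozen by hand into reference_preset().

library(echoblob)

K <- 85            # compression gain (thins per-gray-level tie mass at p95)
PSF <- c(1.8, 4.0) # speckle grain, axial x lateral (px)
SIZE <- c(256L, 128L); SPACING <- c(0.4, 0.4)
ROI_PX <- (256L - 2L * max(4L, round(0.08 * 256))) * 128L
KAPPA <- 0.6       # severity -> inclusion-rate link (fixed)
INCL_SHARE_PX <- 330  # target mean inclusion contribution to FM blob size

mean_echo <- function(scale, n = 12, seeds = 1:12, rate = 0) {
  gp <- group_params(72, scale, rate)
  mean(vapply(seeds, function(s) {
    fr <- simulate_frame(gp, 0, SIZE, SPACING, seed = s, compression_gain = K,
                         psf_sigma_px = PSF)
    compute_echointensity(fr$frame, fr$mask)
  }, numeric(1)))
}

## stage 1: healthy Rayleigh scale from the echointensity target
lo <- 0.5; hi <- 4
for (i in 1:22) {
  mid <- (lo + hi) / 2
  if (mean_echo(mid) < 71.95) lo <- mid else hi <- mid
}
scale_h <- round((lo + hi) / 2, 3)
cat(sprintf("scale_h = %.3f (mean echo %.2f)\n", scale_h, mean_echo(scale_h)))

## stage 2: per-frame tail-fraction noise and sensitivity to the subject effect
tail_frac <- function(scale, effect, seeds, rate = 0, t95) {
  gp <- group_params(72, scale, rate)
  vapply(seeds, function(s) {
    fr <- simulate_frame(gp, effect, SIZE, SPACING, seed = s,
                         compression_gain = K, psf_sigma_px = PSF)
    mean(fr$frame$pixels[fr$mask$mask] >= t95)
  }, numeric(1))
}
# pooled t95 from a large healthy sample at zero effect
gp_h <- group_params(72, scale_h, 0)
pool <- unlist(lapply(1:60, function(s) {
  fr <- simulate_frame(gp_h, 0, SIZE, SPACING, seed = 1000 + s,
                       compression_gain = K, psf_sigma_px = PSF)
  fr$frame$pixels[fr$mask$mask]
}))
t95 <- quantile(pool, 0.95, type = 7, names = FALSE)
cat(sprintf("t95 = %.1f, pooled frac >= t95 = %.4f\n", t95, mean(pool >= t95)))

f0 <- tail_frac(scale_h, 0, 1:80, t95 = t95)
frame_sd_px <- sd(f0) * ROI_PX
h <- 0.04
sens <- (mean(tail_frac(scale_h, h, 1:80, t95 = t95)) -
           mean(tail_frac(scale_h, -h, 1:80, t95 = t95))) / (2 * h)
cat(sprintf("frame tail noise = %.0f px, sensitivity = %.4f frac per unit effect\n",
            frame_sd_px, sens))

## stage 3: between-subject SD from the healthy blob-size CV target
target_sd_h <- 0.2325 * 0.05 * ROI_PX
between_var <- max(target_sd_h^2 - frame_sd_px^2 / 3, 0)
between_sd <- round(sqrt(between_var) / (sens * ROI_PX), 4)
cat(sprintf("between_subject_sd = %.4f (healthy blob SD target %.0f px)\n",
            between_sd, target_sd_h))

## stage 4: FM scale multiplier for the echo-driven share of the FM mean
f_fm_target <- 0.05 * 1.4509 - INCL_SHARE_PX / ROI_PX
delta <- (f_fm_target - 0.05) / sens      # linearized, then refined
for (i in 1:4) {
  f_now <- mean(tail_frac(scale_h, delta, 1:60, t95 = t95))
  delta <- delta + (f_fm_target - f_now) / sens
}
fm_mult <- round(exp(delta), 3)
cat(sprintf("fm scale multiplier = %.3f (echo-only FM frac %.4f, target %.4f)\n",
            fm_mult, mean(tail_frac(scale_h * fm_mult, 0, 1:60, t95 = t95)),
            f_fm_target))
cat(sprintf("  implied FM mean echo = %.2f (printed target 78.48; shortfall accepted)\n",
            mean_echo(scale_h * fm_mult)))

## stage 5: inclusion rate from the per-inclusion supra-threshold yield
yield <- function(rate) {
  gp <- group_params(72, scale_h * fm_mult, rate)
  added <- vapply(1:60, function(s) {
    fr1 <- simulate_frame(gp, 0, SIZE, SPACING, seed = 2000 + s,
                          compression_gain = K, psf_sigma_px = PSF)
    gp0 <- group_params(72, scale_h * fm_mult, 0)
    fr0 <- simulate_frame(gp0, 0, SIZE, SPACING, seed = 2000 + s,
                          compression_gain = K, psf_sigma_px = PSF)
    sum(fr1$frame$pixels[fr1$mask$mask] >= t95) -
      sum(fr0$frame$pixels[fr0$mask$mask] >= t95)
  }, numeric(1))
  mean(added)
}
rate_try <- 0.35
px_at_try <- yield(rate_try)
rate_fm <- round(rate_try * INCL_SHARE_PX / px_at_try, 2)
cat(sprintf("fm inclusion_rate = %.2f /cm2 (%.0f px at rate %.2f)\n",
            rate_fm, px_at_try, rate_try))
rate_h <- round(rate_fm / 3.5, 2)  # healthy muscle shows some septa too
cat(sprintf("healthy inclusion_rate = %.2f /cm2\n", rate_h))

## stage 6: severity -> echo link from the FM blob-size SD target
target_sd_fm <- 0.3079 * 1.4509 * 0.05 * ROI_PX
incl_z_sd <- KAPPA * INCL_SHARE_PX
resid_var <- target_sd_fm^2 - frame_sd_px^2 / 3 -
  (sens * ROI_PX * between_sd)^2 - incl_z_sd^2 - (0.35 * INCL_SHARE_PX)^2
echo_link <- round(sqrt(max(resid_var, 0)) / (sens * ROI_PX), 4)
cat(sprintf("severity_echo_link = %.4f (FM blob SD target %.0f px)\n",
            echo_link, target_sd_fm))

cat("\nFreeze into reference_preset():\n")
cat(sprintf("  compression_gain = %g, psf_sigma_px = c(%.1f, %.1f)\n", K, PSF[1], PSF[2]))
cat(sprintf("  healthy: speckle_scale = %.3f, inclusion_rate = %.2f, between_subject_sd = %.4f\n",
            scale_h, rate_h, between_sd))
cat(sprintf("  fm:      speckle_scale = %.3f * %.3f, inclusion_rate = %.2f, between_subject_sd = %.4f\n",
            scale_h, fm_mult, rate_fm, between_sd))
cat(sprintf("  covmodel: severity_rate_link = %.2f, severity_echo_link = %.4f\n",
            KAPPA, echo_link))

## stage 7: nonlinear refinement against tools/validate_preset.R.
## The linearized stage-6 links overshoot the FM blob-size SD because the
## tail fraction is convex in the subject effect and the exp() severity links
## compound it (validated FM CV 0.45 vs target 0.31 at echo_link 0.0555,
## rate_link 0.6). Frozen values after two validation rounds (20 and 25
## cohorts), with the FM scale multiplier refined toward the printed
## FM/healthy mean ratio 1.4509 measured against the realized healthy mean:
##   severity_echo_link 0.030, severity_rate_link 0.40, fm multiplier 1.043
## Final 40-cohort validation: healthy blob 1440 +/- 306 (CV 0.213),
## FM 2115 +/- 614 (CV 0.290), ratio 1.469, pooled frac >= t95 0.0521,
## Mann-Whitney p < 0.05 in 40/40, Spearman blob~CSI > 0 in 40/40.
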