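#!/usr/bin/env Rscript
# Validation of the frozen reference preset against its calibration targets
# (run after tools/tune_preset.R values are frozen and the package is
# reinstalled). Reports, over n_cohorts seeded 34+34 cohorts: group means/SDs
# of the subject-level metrics, the pooled-healthy tail fraction, the
# Mann-Whitney significance rate for total blob size, and the sign rate of the
# FM blob-size ~ CSI Spearman correlation.

library(echoblob)
n_cohorts <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(n_cohorts)) n_cohorts <- 20

res <- lapply(seq_len(n_cohorts), function(s) {
  sim <- simulate_cohort(34, seed = s)
  healthy <- Filter(function(x) x$group == "healthy", sim$scans)
  th <- reference_thresholds(healthy)
  m <- cohort_metrics(sim$scans, th, covariates = sim$covariates)
  fm <- m[m$group == "fm", ]; hc <- m[m$group == "healthy", ]
  pool <- unlist(lapply(healthy, function(x)
    lapply(x$frames, function(fr) fr$frame$pixels[fr$mask$mask])))
  c(h_echo = mean(hc$echointensity), f_echo = mean(fm$echointensity),
    h_echo_sd = sd(hc$echointensity), f_echo_sd = sd(fm$echointensity),
    h_blob = mean(hc$total_blob_size_px_p95),
    h_blob_sd = sd(hc$total_blob_size_px_p95),
    f_blob = mean(fm$total_blob_size_px_p95),
    f_blob_sd = sd(fm$total_blob_size_px_p95),
    h_count = mean(hc$blob_count_p95), f_count = mean(fm$blob_count_p95),
    frac95 = mean(pool >= th$thresholds[1]),
    mw_p = mann_whitney(fm$total_blob_size_px_p95,
                        hc$total_blob_size_px_p95)$p,
    rho_csi = cor(fm$total_blob_size_px_p95, fm$csi_total,
                  method = "spearman"))
})
res <- do.call(rbind, res)
avg <- colMeans(res)
cat(sprintf("cohorts: %d\n", n_cohorts))
cat(sprintf("healthy echo %.2f (sd %.2f) | fm echo %.2f (sd %.2f)\n",
            avg["h_echo"], avg["h_echo_sd"], avg["f_echo"], avg["f_echo_sd"]))
cat(sprintf("healthy blob %.0f +/- %.0f (CV %.3f; targets 1383, CV 0.233)\n",
            avg["h_blob"], avg["h_blob_sd"], avg["h_blob_sd"] / avg["h_blob"]))
cat(sprintf("fm blob %.0f +/- %.0f (CV %.3f; targets 2006, CV 0.308)\n",
            avg["f_blob"], avg["f_blob_sd"], avg["f_blob_sd"] / avg["f_blob"]))
cat(sprintf("ratio fm/healthy = %.3f (target 1.451)\n",
            avg["f_blob"] / avg["h_blob"]))
cat(sprintf("blob counts: healthy %.1f, fm %.1f\n",
            avg["h_count"], avg["f_count"]))
cat(sprintf("pooled frac >= t95: mean %.4f, range [%.4f, %.4f]\n",
            avg["frac95"], min(res[, "frac95"]), max(res[, "frac95"])))
cat(sprintf("MW p < 0.05 in %d/%d cohorts (median p %.2g)\n",
            sum(res[, "mw_p"] < 0.05), n_cohorts, median(res[, "mw_p"])))
cat(sprintf("Spearman blob~CSI > 0 in %d/%d (mean rho %.3f)\n",
            sum(res[, "rho_csi"] > 0), n_cohorts, avg["rho_csi"]))
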