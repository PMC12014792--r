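Package: echoblob
Title: Blob-Texture Quantification of B-Mode Muscle Ultrasound with Cohort Statistics
Version: 0.1.0
Authors@R: person("echoblob", "maintainers", email = "echoblob@example.org", role = c("aut", "cre"))
Description: Quantifies hyperechoic texture in 8-bit B-mode ultrasound images of
    skeletal muscle by percentile-referenced thresholding and connected-component
    ("blob") analysis: echointensity, blob count, total blob size, and per-mm2
    normalizations at healthy-cohort 95th/99th percentile thresholds. Includes a
    seeded synthetic speckle-cohort generator (Rayleigh amplitude, log compression,
    fiber-aligned hyperechoic inclusions, latent-severity clinical covariates) and
    the full cohort statistics battery: normality-gated two-group tests, Pearson or
    Spearman correlations, backward-elimination linear regression with VIF and
    Durbin-Watson diagnostics, and Benjamini-Hochberg FDR adjustment.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
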