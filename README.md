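# echoblob

Blob-texture quantification of B-mode muscle ultrasound, with the full cohort
statistics battery and a seeded synthetic speckle-cohort generator.

## The problem

Fibromyalgia (FM) has no objective imaging biomarker; assessment rests on
patient-reported indices (pain VAS, Central Sensitization Inventory, FIQ,
SF-36, Beck inventories). Quantitative ultrasonography of tender-point
muscles — here the upper trapezius — offers one candidate: **blob analysis**,
which thresholds the 8-bit grayscale image against percentiles of a healthy
reference distribution and measures the spatially connected hyperechoic
regions ("blobs") that remain.

For a frame `I` (grayscale 0–255) with ROI `R` (muscle area, fascia
excluded), and pooled healthy ROI pixels defining thresholds `t_p` at the
95th and 99th percentiles (linear interpolation between order statistics):

- echointensity `EI = mean(I[R])`
- binary map `B_p = [ I >= t_p ] ∩ R`
- blobs = connected components of `B_p` (8-neighbor adjacency)
- metrics: blob count `N_p`, total blob size `S_p = Σ |blob|` (px and mm²),
  and `N_p / area(R)`, `S_p / area(R)` per mm²

Per subject, metrics are averaged over three consecutive static frames. The
cohort stage compares FM vs healthy (Shapiro–Wilk-gated Student t or
Mann–Whitney U), correlates metrics with clinical covariates (Pearson or
Spearman by the same gate), fits backward-elimination OLS regressions with
VIF and Durbin–Watson diagnostics, and applies the Benjamini–Hochberg
step-up FDR adjustment across the reported family.

Because the source cohort's images are not public, the package includes a
calibrated generator: Rayleigh speckle (complex-Gaussian envelope with a
fiber-aligned PSF grain), Poisson-placed hyperechoic inclusions, log
compression to 0–255, and a latent-severity covariate model that cross-links
symptom scores to the imaging signal. See
`vignettes/echoblob-methods.Rmd` for the model, its calibration, and what it
deliberately does not reproduce.

## Worked example

```r
library(echoblob)

sim     <- simulate_cohort(n_per_group = 34, seed = 17)   # 68 subjects, 204 frames
healthy <- Filter(function(s) s$group == "healthy", sim$scans)
th      <- reference_thresholds(healthy, percentiles = c(95, 99))
th
#> <threshold_set: p95=115.00, p99=129.00 from 2820096 pooled healthy ROI pixels>

metrics  <- cohort_metrics(sim$scans, th, covariates = sim$covariates)
analysis <- run_full_analysis(metrics)
analysis
#> == Group comparisons (FM vs healthy) ==
#>                 variable           test              fm_summary           healthy_summary    p_raw    p_fdr
#>           echointensity mann_whitney_u     75.19 (70.44-82.26)       72.63 (67.68-75.82) 8.90e-05 3.16e-04
#>  total_blob_size_px_p95 mann_whitney_u 2051.67 (1175.33-3764.67) 1471.17 (783.33-1993.67) 1.30e-05 5.57e-05
#>  ...
```

The FM group is brighter (echointensity 75.2 vs 72.6, Mann–Whitney
p = 8.9e-5) and carries ~40% more supra-threshold blob area (2052 vs 1471 px,
p = 1.3e-5) — the direction and effect size the generator is calibrated to.
Downstream, blob metrics correlate moderately with CSI and fatigue VAS within
the FM group, and backward elimination retains symptom scores as predictors,
e.g.:

```r
analysis$regressions$blob_count_p95
#> <backward OLS for 'blob_count_p95': n = 34, R2 = 0.547, model p = 4.608e-06, DW = 1.61>
#>         term      beta        se  beta_std       p_raw      p_fdr      vif
#>  fatigue_vas 5.6445993 1.8699217 0.4312929 0.005044537 0.01015958 1.398225
#>    csi_total 0.3880984 0.1340853 0.4135456 0.006898172 0.01315763 1.398225
```

Reproducing the published FDR-adjusted p-values exactly (the one published
computation that is deterministic from printed numbers — 23 raw p-values,
"< 0.001" coded 0.001, one family):

```r
fam <- reported_p_values()
all(round(bh_fdr(fam$p_raw), 3) == fam$p_adj_printed)
#> [1] TRUE
```

On-disk pipeline (PNG frames + masks + CSV manifest in, CSV/JSON/markdown
reports out), end-to-end under one seed:

```r
cfg <- run_config("demo", seed = 17)
pipeline_run(cfg)    # demo/cohort/, demo/thresholds.json, demo/metrics.csv, demo/report/
```

or from the shell:

```sh
Rscript -e 'echoblob::echoblob_main()' run --out demo --seed 17
Rscript -e 'echoblob::echoblob_main()' --help
```

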