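#' Build a validated run configuration
#'
#' @param out output directory.
#' @param seed master seed (recorded in every output header).
#' @param n_per_group subjects per group for the simulate stage.
#' @param percentiles strictly increasing percentile levels in `(0, 100)`.
#' @param connectivity 4 or 8.
#' @param aggregation `"mean"` or `"median"` subject aggregation.
#' @param fdr_family `"global"` or `"per_table"`.
#' @param preset generator preset (see [reference_preset()]).
#' @return list of class `run_config` with a `config_hash` that changes iff
#'   any setting changes.
#' @export
run_config <- function(out, seed = 17, n_per_group = 34,
                       percentiles = c(95, 99), connectivity = 8,
                       aggregation = "mean", fdr_family = "global",
                       preset = reference_preset()) {
  if (any(percentiles <= 0) || any(percentiles >= 100) ||
      is.unsorted(percentiles, strictly = TRUE))
    stop("percentiles must be strictly increasing and inside (0, 100)")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  aggregation <- match.arg(aggregation, c("mean", "median"))
  fdr_family <- match.arg(fdr_family, c("global", "per_table"))
  cfg <- list(out = out, seed = as.integer(seed), n_per_group = n_per_group,
              percentiles = percentiles, connectivity = connectivity,
              aggregation = aggregation, fdr_family = fdr_family,
              preset = preset)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg[setdiff(names(cfg), "out")], tf, compress = FALSE)
  cfg$config_hash <- unname(tools::md5sum(tf))
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: simulate, thresholds, analyze, stats
#'
#' Executes the four stages in order under one seed: synthetic cohort written
#' to `<out>/cohort/`, healthy-referenced percentile thresholds to
#' `<out>/thresholds.json`, per-subject blob metrics to `<out>/metrics.csv`,
#' and the statistics bundle to `<out>/report/`. Every output carries a
#' provenance header (package version, seed, config hash).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `cohort_dir`, `thresholds`, `metrics` (data.frame),
#'   `analysis`, invisibly.
#' @export
pipeline_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  prov <- c(seed = config$seed, config_hash = config$config_hash)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  say("[simulate] %d + %d subjects (seed %d)",
      config$n_per_group, config$n_per_group, config$seed)
  cohort_dir <- file.path(config$out, "cohort")
  sim <- simulate_cohort(config$n_per_group, seed = config$seed,
                         preset = config$preset, dir = cohort_dir)

  say("[thresholds] pooling healthy ROI pixels")
  healthy <- Filter(function(s) s$group == "healthy", sim$scans)
  th <- reference_thresholds(healthy, percentiles = config$percentiles)
  jsonlite::write_json(
    list(thresholds = as.list(th$thresholds),
         percentiles = th$percentiles,
         source_n_pixels = th$source_n_pixels,
         percentile_definition = th$definition,
         seed = config$seed, config_hash = config$config_hash,
         version = as.character(utils::packageVersion("echoblob"))),
    file.path(config$out, "thresholds.json"), auto_unbox = TRUE, digits = NA)

  say("[analyze] blob metrics for %d subjects", length(sim$scans))
  metrics <- cohort_metrics(sim$scans, th, connectivity = config$connectivity,
                            covariates = sim$covariates,
                            aggregate = config$aggregation)
  metrics_path <- file.path(config$out, "metrics.csv")
  writeLines(c(sprintf("# echoblob %s",
                       as.character(utils::packageVersion("echoblob"))),
               sprintf("# %s: %s", names(prov), prov)), metrics_path)
  suppressWarnings(utils::write.table(metrics, metrics_path, append = TRUE,
                                      sep = ",", row.names = FALSE,
                                      qmethod = "double"))

  say("[stats] group comparisons, correlations, regressions, FDR")
  analysis <- run_full_analysis(metrics,
                                config = list(fdr_family = config$fdr_family))
  write_analysis(analysis, file.path(config$out, "report"), provenance = prov)

  invisible(list(cohort_dir = cohort_dir, thresholds = th, metrics = metrics,
                 analysis = analysis))
}
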