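default_endpoints <- c("echointensity", "blob_count_p95",
                       "total_blob_size_px_p95", "total_blob_size_per_mm2_p95",
                       "blob_count_per_mm2_p95")

default_correlates <- c("bmi", "weight", "complaint_months", "diagnosis_months",
                        "wpi", "sss", "pain_vas", "fatigue_vas", "sleep_vas",
                        "bdi", "bai", "csi_total", "fiq")

#' Run the full cohort analysis battery
#'
#' Mirrors the reference analysis plan on a cohort table (one row per subject
#' with group, blob metrics, covariates): per-group descriptives, normality-
#' gated two-group comparisons for every endpoint and shared covariate, a
#' categorical test of physical-activity level, endpoint-vs-covariate
#' correlations within the FM group, backward-elimination regressions for blob
#' count, blob density, and echointensity (predictors: covariates significant
#' in that endpoint's correlations, plus a medication indicator), and a
#' Benjamini-Hochberg FDR adjustment over the configured family.
#'
#' @param cohort data.frame from [cohort_metrics()] (with covariates joined).
#' @param config list; recognized entries: `endpoints`, `correlates`,
#'   `fdr_family` (`"global"` — one family across comparisons, correlations
#'   and regression terms — or `"per_table"`), `p_remove`, `bands`
#'   (correlation strength cutoffs).
#' @return list of class `echoblob_analysis` with `descriptives`,
#'   `comparisons`, `categorical`, `correlations`, `regressions`,
#'   `fdr_family`, `config`.
#' @export
run_full_analysis <- function(cohort, config = list()) {
  cfg <- utils::modifyList(list(endpoints = default_endpoints,
                                correlates = default_correlates,
                                fdr_family = "global", p_remove = 0.05,
                                bands = c(0.3, 0.6)), config)
  if (!all(c("healthy", "fm") %in% cohort$group))
    stop("cohort must contain both groups")
  endpoints <- intersect(cfg$endpoints, names(cohort))
  correlates <- intersect(cfg$correlates, names(cohort))
  fm <- cohort[cohort$group == "fm", , drop = FALSE]
  hc <- cohort[cohort$group == "healthy", , drop = FALSE]

  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  shared <- setdiff(num_cols, c(endpoints, "latent_severity",
                                "roi_n_pixels", "roi_area_mm2"))
  shared <- shared[vapply(shared, function(v)
    sum(!is.na(fm[[v]])) >= 3 && sum(!is.na(hc[[v]])) >= 3, logical(1))]

  descr <- do.call(rbind, lapply(c(endpoints, shared), function(v)
    do.call(rbind, lapply(list(healthy = hc, fm = fm), function(g) {
      x <- g[[v]][!is.na(g[[v]])]
      data.frame(variable = v, group = g$group[1], n = length(x),
                 mean = mean(x), sd = stats::sd(x), median = stats::median(x),
                 min = min(x), max = max(x))
    }))))
  rownames(descr) <- NULL

  comparisons <- do.call(rbind, lapply(c(endpoints, shared), function(v) {
    tr <- compare_groups(fm[[v]], hc[[v]], label = v)
    data.frame(variable = v, test = tr$test_name, statistic = tr$statistic,
               fm_summary = tr$summary_a, healthy_summary = tr$summary_b,
               direction = tr$direction, p_raw = tr$p_raw, p_fdr = NA_real_)
  }))

  categorical <- NULL
  if ("ipaq_category" %in% names(cohort)) {
    tab <- table(cohort$group, cohort$ipaq_category)
    ct <- categorical_test(as.matrix(tab))
    categorical <- data.frame(variable = "ipaq_category", test = ct$test_name,
                              statistic = ct$statistic, p_raw = ct$p_raw,
                              p_fdr = NA_real_)
  }

  correlations <- do.call(rbind, lapply(endpoints, function(ep)
    do.call(rbind, lapply(correlates, function(v) {
      ok <- !is.na(fm[[ep]]) & !is.na(fm[[v]])
      if (sum(ok) < 4 || stats::sd(fm[[v]][ok]) == 0) return(NULL)
      cr <- correlate(fm[[ep]], fm[[v]], bands = cfg$bands)
      data.frame(endpoint = ep, covariate = v, method = cr$method, r = cr$r,
                 strength = cr$strength, n = cr$n, p_raw = cr$p_raw,
                 p_fdr = NA_real_)
    }))))
  rownames(correlations) <- NULL

  fm$on_medication <- as.numeric(fm$drug_class != "none")
  responses <- intersect(c("blob_count_p95", "total_blob_size_per_mm2_p95",
                           "echointensity"), endpoints)
  regressions <- list()
  for (resp in responses) {
    sig <- correlations$covariate[correlations$endpoint == resp &
                                    correlations$p_raw < 0.05]
    preds <- unique(c(sig, if (any(fm$on_medication != fm$on_medication[1]))
      "on_medication"))
    preds <- preds[vapply(preds, function(v)
      stats::sd(fm[[v]], na.rm = TRUE) > 0, logical(1))]
    if (length(preds) && nrow(fm) > length(preds) + 2) {
      regressions[[resp]] <- tryCatch(
        backward_ols(fm, resp, preds, p_remove = cfg$p_remove),
        error = function(e) {
          warning(sprintf("regression for %s skipped: %s", resp,
                          conditionMessage(e)))
          NULL
        })
    }
  }

  # assemble the FDR family and push adjusted values back
  fam <- rbind(
    data.frame(source = "comparison", label = comparisons$variable,
               p_raw = comparisons$p_raw),
    if (!is.null(categorical))
      data.frame(source = "categorical", label = categorical$variable,
                 p_raw = categorical$p_raw),
    if (!is.null(correlations) && nrow(correlations))
      data.frame(source = "correlation",
                 label = paste(correlations$endpoint, correlations$covariate,
                               sep = "~"),
                 p_raw = correlations$p_raw),
    do.call(rbind, lapply(names(regressions), function(r) {
      co <- regressions[[r]]$coefficients
      if (!nrow(co)) return(NULL)
      data.frame(source = "regression", label = paste(r, co$term, sep = "~"),
                 p_raw = co$p_raw)
    }))
  )
  fam$p_raw <- pmax(fam$p_raw, .Machine$double.xmin)  # guard exact zeros
  if (cfg$fdr_family == "global") {
    fam$p_fdr <- bh_fdr(fam$p_raw)
  } else {
    fam$p_fdr <- NA_real_
    for (s in unique(fam$source))
      fam$p_fdr[fam$source == s] <- bh_fdr(fam$p_raw[fam$source == s])
  }
  lookup <- function(source, label)
    fam$p_fdr[match(paste(source, label), paste(fam$source, fam$label))]
  comparisons$p_fdr <- lookup("comparison", comparisons$variable)
  if (!is.null(categorical))
    categorical$p_fdr <- lookup("categorical", categorical$variable)
  if (!is.null(correlations) && nrow(correlations))
    correlations$p_fdr <- lookup("correlation",
                                 paste(correlations$endpoint,
                                       correlations$covariate, sep = "~"))
  for (r in names(regressions)) {
    co <- regressions[[r]]$coefficients
    if (nrow(co))
      regressions[[r]]$coefficients$p_fdr <-
        lookup("regression", paste(r, co$term, sep = "~"))
  }

  structure(list(descriptives = descr, comparisons = comparisons,
                 categorical = categorical, correlations = correlations,
                 regressions = regressions, fdr_family = fam, config = cfg),
            class = "echoblob_analysis")
}

#' @export
print.echoblob_analysis <- function(x, ...) {
  cat("== Group comparisons (FM vs healthy) ==\n")
  print(x$comparisons[, c("variable", "test", "fm_summary", "healthy_summary",
                          "p_raw", "p_fdr")], row.names = FALSE, digits = 3)
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    sig <- x$correlations[x$correlations$p_raw < 0.05, , drop = FALSE]
    cat(sprintf("\n== Significant FM correlations (%d of %d) ==\n",
                nrow(sig), nrow(x$correlations)))
    if (nrow(sig)) print(sig[, c("endpoint", "covariate", "method", "r",
                                 "strength", "p_raw", "p_fdr")],
                         row.names = FALSE, digits = 3)
  }
  for (r in names(x$regressions)) {
    cat("\n")
    print(x$regressions[[r]])
  }
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Emits `comparisons.csv`, `correlations.csv`, `regressions.csv`,
#' `fdr_family.csv`, `descriptives.csv` and a human-readable `report.md`,
#' each with a provenance comment header.
#'
#' @param analysis an `echoblob_analysis` from [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @param provenance named character vector prepended as `# key: value` lines.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir, provenance = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("# echoblob %s",
                   as.character(utils::packageVersion("echoblob"))),
           sprintf("# %s: %s", names(provenance), provenance))
  emit <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, qmethod = "double"))
  }
  emit(analysis$descriptives, "descriptives.csv")
  emit(analysis$comparisons, "comparisons.csv")
  if (!is.null(analysis$correlations) && nrow(analysis$correlations))
    emit(analysis$correlations, "correlations.csv")
  reg <- do.call(rbind, lapply(names(analysis$regressions), function(r) {
    m <- analysis$regressions[[r]]
    if (is.null(m) || !nrow(m$coefficients)) return(NULL)
    cbind(response = r, m$coefficients,
          durbin_watson = m$durbin_watson, model_p = m$model_p,
          eliminated = paste(m$eliminated, collapse = ";"))
  }))
  if (!is.null(reg)) emit(reg, "regressions.csv")
  emit(analysis$fdr_family, "fdr_family.csv")

  rp <- file.path(dir, "report.md")
  con <- file(rp, "w"); on.exit(close(con))
  writeLines(c("# Cohort analysis report", "",
               gsub("^# ", "", hdr), "",
               "## Group comparisons", "",
               utils::capture.output(print(analysis$comparisons,
                                           row.names = FALSE, digits = 3)),
               "", "## FDR family",
               sprintf("%d p-values adjusted in '%s' mode.",
                       nrow(analysis$fdr_family),
                       analysis$config$fdr_family)), con)
  invisible(dir)
}
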