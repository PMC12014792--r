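#' Normality gate for test routing
#'
#' Shapiro-Wilk at `alpha = 0.05` decides whether a sample is routed to the
#' parametric (Student t / Pearson) or rank-based (Mann-Whitney / Spearman)
#' branch. Degenerate samples (zero variance), for which the test is
#' undefined, take the conservative non-normal route.
#'
#' @param x numeric sample, `n >= 3` after removing `NA`.
#' @param alpha gate level.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality_gate needs n >= 3")
  if (stats::sd(x) == 0) return("non_normal")
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  if (stats::shapiro.test(x)$p.value < alpha) "non_normal" else "normal"
}

# midrank-based Mann-Whitney U of sample a vs b
mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (exact enumeration or corrected normal approximation)
#'
#' Two-sided. The exact route enumerates all assignments of the pooled values
#' to the two groups (ties handled by midranks) and is used automatically when
#' both samples have `n <= exact_max_n`; the p-value is the probability of a U
#' at least as far from its null mean as observed, so identical samples give
#' `p = 1`. The large-sample route uses the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b numeric samples.
#' @param exact_max_n exact-enumeration cutoff per group (default 8).
#' @param force `"auto"`, `"exact"` or `"approx"`.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max_n = 8, force = c("auto", "exact", "approx")) {
  force <- match.arg(force)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("empty group")
  u <- mw_u(a, b)
  mu <- na * nb / 2
  use_exact <- switch(force, exact = TRUE, approx = FALSE,
                      auto = (na <= exact_max_n && nb <= exact_max_n))
  if (use_exact) {
    pooled_r <- rank(c(a, b))
    offs <- na * (na + 1) / 2
    combos <- utils::combn(na + nb, na)
    U_all <- colSums(matrix(pooled_r[combos], nrow = na)) - offs
    p <- mean(abs(U_all - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, p = p, method = "exact enumeration"))
  }
  N <- na + nb
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sd_u <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
  if (sd_u == 0 || u == mu) return(list(U = u, p = 1, method = "normal approximation"))
  z <- (u - mu - sign(u - mu) * 0.5) / sd_u
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation (tie + continuity corrected)")
}

#' Two-group comparison with normality-gated routing
#'
#' Both samples normal (per [normality_gate()]) routes to the independent
#' Student t test (equal variances); otherwise to [mann_whitney()]. Group
#' summaries follow the selected route's reporting style: mean +/- SD for the
#' t route, median (min-max) for the rank route.
#'
#' @param a,b numeric samples (`n >= 3` each after `NA` removal).
#' @param force `"auto"` (gate), `"student_t"` or `"mann_whitney"`.
#' @param label optional endpoint name carried into the result.
#' @return list of class `test_result`: `test_name`, `statistic`, `p_raw`,
#'   `p_fdr` (NA until adjusted), `summary_a`, `summary_b`, `direction`
#'   (mean of `a` minus mean of `b`), `gate`.
#' @export
compare_groups <- function(a, b, force = c("auto", "student_t", "mann_whitney"),
                           label = "") {
  force <- match.arg(force)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("both groups need n >= 3")
  gate <- if (force == "auto")
    c(normality_gate(a), normality_gate(b)) else c(force, force)
  use_t <- if (force == "auto") all(gate == "normal") else force == "student_t"
  if (use_t) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_name = "student_t", statistic = unname(tt$statistic),
                p_raw = tt$p.value,
                summary_a = sprintf("%.2f ± %.2f", mean(a), stats::sd(a)),
                summary_b = sprintf("%.2f ± %.2f", mean(b), stats::sd(b)))
  } else {
    mw <- mann_whitney(a, b)
    res <- list(test_name = "mann_whitney_u", statistic = mw$U, p_raw = mw$p,
                summary_a = sprintf("%.2f (%.2f-%.2f)", stats::median(a),
                                    min(a), max(a)),
                summary_b = sprintf("%.2f (%.2f-%.2f)", stats::median(b),
                                    min(b), max(b)))
  }
  res$p_fdr <- NA_real_
  res$direction <- mean(a) - mean(b)
  res$gate <- gate
  res$label <- label
  structure(res, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s%s: stat = %.4g, p = %.4g%s>\n",
              x$test_name, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$statistic, x$p_raw,
              if (!is.na(x$p_fdr)) sprintf(", p_fdr = %.4g", x$p_fdr) else ""))
  invisible(x)
}

#' Categorical association test (chi-square or Fisher exact)
#'
#' Pearson chi-square when every expected cell count is at least 5, otherwise
#' Fisher's exact test (the Freeman-Halton extension for tables wider than
#' 2 x 2, summing probabilities of tables no more probable than the observed
#' one). The Pearson statistic is reported in both cases for reference.
#'
#' @param tab contingency matrix (2 x C, nonnegative integers, no zero
#'   margins).
#' @return list of class `test_result` with `test_name`, `statistic`
#'   (Pearson chi-square), `p_raw`, `expected`.
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold nonnegative integer counts")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero-margin table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_stat <- sum((tab - expected)^2 / expected)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    name <- "fisher_exact"
  } else {
    p <- stats::pchisq(chisq_stat, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                       lower.tail = FALSE)
    name <- "chi_square"
  }
  structure(list(test_name = name, statistic = chisq_stat, p_raw = p,
                 p_fdr = NA_real_, expected = expected, label = ""),
            class = "test_result")
}

#' Correlation with normality-gated method choice
#'
#' Pearson when both variables pass the normality gate, Spearman's rho
#' otherwise. The coefficient is labelled by configurable absolute-value
#' bands (default: below 0.3 weak, 0.3-0.6 moderate, above 0.6 strong).
#'
#' @param x,y numeric vectors of equal length (pairs with `NA` dropped;
#'   `n >= 4` required).
#' @param bands two increasing cutoffs for the strength label.
#' @param force `"auto"`, `"pearson"` or `"spearman"`.
#' @return list of class `correlation_result`: `method`, `r`, `p_raw`,
#'   `p_fdr`, `strength`, `n`.
#' @export
correlate <- function(x, y, bands = c(0.3, 0.6),
                      force = c("auto", "pearson", "spearman")) {
  force <- match.arg(force)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("correlate needs n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  method <- switch(force,
                   pearson = "pearson", spearman = "spearman",
                   auto = if (normality_gate(x) == "normal" &&
                              normality_gate(y) == "normal")
                     "pearson" else "spearman")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  strength <- if (abs(r) < bands[1]) "weak"
  else if (abs(r) <= bands[2]) "moderate" else "strong"
  structure(list(method = method, r = r, p_raw = ct$p.value,
                 p_fdr = NA_real_, strength = strength, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s r = %.3f (%s), p = %.4g, n = %d>\n",
              x$method, x$r, x$strength, x$p_raw, x$n))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts the m raw p-values ascending, sets the i-th adjusted value to
#' `min over j >= i of m * p_(j) / j` capped at 1, and returns the adjusted
#' values in the input order. Adjusted values are monotone in the raw values
#' and never smaller than them.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Backward-elimination ordinary least squares
#'
#' Fits the full model, then iteratively removes the predictor with the
#' largest p-value at or above `p_remove` and refits, until every retained
#' predictor has `p < p_remove` (or none remain). Reports unstandardized and
#' standardized coefficients, variance inflation factors, the Durbin-Watson
#' statistic, the overall model F-test p-value, and the elimination trace.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param p_remove removal threshold (default 0.05; `1` keeps the full model).
#' @return list of class `regression_result`: `coefficients` (data.frame with
#'   `term`, `beta`, `se`, `beta_std`, `p_raw`, `p_fdr`, `vif`),
#'   `durbin_watson`, `model_p`, `r_squared`, `eliminated` (in removal order),
#'   `n`.
#' @export
backward_ols <- function(data, response, predictors, p_remove = 0.05) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  d <- stats::na.omit(data[, c(response, predictors), drop = FALSE])
  n <- nrow(d)
  if (n <= length(predictors) + 2)
    stop(sprintf("n = %d too small for %d predictors", n, length(predictors)))
  sds <- vapply(d[predictors], stats::sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("constant predictor(s): %s",
                 paste(predictors[sds == 0], collapse = ", ")))
  if (qr(as.matrix(cbind(1, d[predictors])))$rank < length(predictors) + 1)
    stop("rank-deficient design (collinear or duplicated predictors)")

  eliminated <- character(0)
  retained <- predictors
  repeat {
    fml <- stats::reformulate(retained, response)
    fit <- stats::lm(fml, data = d)
    ps <- summary(fit)$coefficients[-1, 4, drop = TRUE]
    names(ps) <- retained
    if (!length(ps) || max(ps) < p_remove) break
    worst <- names(ps)[which.max(ps)]
    eliminated <- c(eliminated, worst)
    retained <- setdiff(retained, worst)
    if (!length(retained)) {
      fit <- stats::lm(stats::reformulate("1", response), data = d)
      break
    }
  }

  sm <- summary(fit)
  if (length(retained)) {
    co <- sm$coefficients[-1, , drop = FALSE]
    beta_std <- co[, 1] * vapply(d[retained], stats::sd, numeric(1)) /
      stats::sd(d[[response]])
    vif <- vapply(retained, function(v) {
      if (length(retained) == 1) return(1)
      r2 <- summary(stats::lm(stats::reformulate(setdiff(retained, v), v),
                              data = d))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    coefficients <- data.frame(term = retained, beta = unname(co[, 1]),
                               se = unname(co[, 2]),
                               beta_std = unname(beta_std),
                               p_raw = unname(co[, 4]), p_fdr = NA_real_,
                               vif = unname(vif))
  } else {
    coefficients <- data.frame(term = character(0), beta = numeric(0),
                               se = numeric(0), beta_std = numeric(0),
                               p_raw = numeric(0), p_fdr = numeric(0),
                               vif = numeric(0))
  }
  e <- stats::residuals(fit)
  fstat <- sm$fstatistic
  model_p <- if (!is.null(fstat))
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  else NA_real_
  structure(list(coefficients = coefficients,
                 durbin_watson = sum(diff(e)^2) / sum(e^2),
                 model_p = model_p, r_squared = sm$r.squared,
                 eliminated = eliminated, n = n, response = response),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<backward OLS for '%s': n = %d, R2 = %.3f, model p = %.4g, DW = %.2f>\n",
              x$response, x$n, x$r_squared, x$model_p, x$durbin_watson))
  if (nrow(x$coefficients)) print(x$coefficients, row.names = FALSE)
  else cat("  (no predictors retained)\n")
  if (length(x$eliminated))
    cat("  eliminated:", paste(x$eliminated, collapse = " -> "), "\n")
  invisible(x)
}
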