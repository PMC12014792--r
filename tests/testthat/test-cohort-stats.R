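test_that("normality gate routes clean, contaminated, and degenerate samples", {
  # level check: seeded standard-normal samples pass the gate most of the time
  set.seed(77)
  passes <- sum(vapply(1:100, function(i)
    normality_gate(rnorm(50)) == "normal", logical(1)))
  expect_gte(passes, 90)
  # extreme outlier forces the rank route
  expect_identical(normality_gate(c(rep(1, 29), 1000)), "non_normal")
  # constant sample: test undefined -> conservative route
  expect_identical(normality_gate(rep(5, 30)), "non_normal")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("Mann-Whitney exact enumeration matches hand-computed cases", {
  # a = 1:3 vs b = 4:6: U = 0, only U in {0, 9} as extreme -> p = 2/20
  mw <- mann_whitney(1:3, 4:6)
  expect_identical(mw$method, "exact enumeration")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  # identical samples -> p = 1 exactly
  expect_equal(mann_whitney(c(2, 5, 9, 9), c(2, 5, 9, 9))$p, 1)
  # symmetric in the group order
  expect_equal(mann_whitney(4:6, 1:3)$p, 0.1)
  # agrees with stats::wilcox.test where the latter is exact (no ties)
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:100, sample(3:8, 1))
    b <- sample(101:200, sample(3:8, 1)) / 2.7
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12, label = sprintf("iter %d", i))
  }
})

test_that("Mann-Whitney normal approximation tracks the exact distribution", {
  set.seed(21)
  for (i in 1:30) {
    # continuous data: tight agreement at every small-n shape
    a <- rnorm(sample(4:8, 1))
    b <- rnorm(sample(4:8, 1), sample(0:1, 1))
    expect_lte(abs(mann_whitney(a, b, force = "exact")$p -
                     mann_whitney(a, b, force = "approx")$p), 0.05)
    # tied integer data: the approximation degrades gracefully (the exact
    # route owns this regime in practice)
    ta <- sample(0:20, sample(4:8, 1), replace = TRUE)
    tb <- sample(5:25, sample(4:8, 1), replace = TRUE)
    expect_lte(abs(mann_whitney(ta, tb, force = "exact")$p -
                     mann_whitney(ta, tb, force = "approx")$p), 0.15)
  }
})

test_that("compare_groups gates between t and Mann-Whitney with matched summaries", {
  set.seed(5)
  a <- rnorm(30, 10); b <- rnorm(30, 12)
  res <- compare_groups(a, b)
  expect_identical(res$test_name, "student_t")
  expect_match(res$summary_a, "±")
  expect_equal(res$p_raw, t.test(a, b, var.equal = TRUE)$p.value)
  # heavy-tailed data takes the rank route with median (min-max) summaries
  x <- exp(rnorm(30, 0, 2)); y <- exp(rnorm(30, 1, 2))
  res2 <- compare_groups(x, y)
  expect_identical(res2$test_name, "mann_whitney_u")
  expect_match(res2$summary_a, "\\(")
  # forcing a route bypasses the gate
  expect_identical(compare_groups(x, y, force = "student_t")$test_name,
                   "student_t")
  expect_error(compare_groups(c(1, 2), b), "n >= 3")
})

test_that("categorical_test picks the route by expected counts", {
  # perfect independence
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(categorical_test(even)$p_raw, 1)
  # the activity-level 2x3 table: expected cells below 5 -> Fisher route,
  # Pearson statistic 10.02 by direct computation
  ip <- matrix(c(22, 9, 11, 23, 1, 2), 2)
  res <- categorical_test(ip)
  expect_identical(res$test_name, "fisher_exact")
  expect_equal(res$statistic, 10.02024, tolerance = 1e-5)
  expect_lt(res$p_raw, 0.05)
  # perfect association is significant under either route
  expect_lt(categorical_test(matrix(c(10, 0, 0, 10), 2))$p_raw, 0.001)
  # large balanced table routes to chi-square
  big <- matrix(c(30, 10, 10, 30), 2)
  res2 <- categorical_test(big)
  expect_identical(res2$test_name, "chi_square")
  expect_equal(res2$p_raw, chisq.test(big, correct = FALSE)$p.value)
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2)), "zero-margin")
  expect_error(categorical_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("correlate gates between Pearson and Spearman with strength bands", {
  set.seed(9)
  x <- rnorm(40)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_identical(correlate(x, 2 * x + 1)$method, "pearson")
  # strictly decreasing nonlinear transform -> Spearman -1
  xm <- exp(rnorm(40, 0, 1.5))
  res <- correlate(xm, -xm^3)
  expect_identical(res$method, "spearman")
  expect_equal(res$r, -1)
  expect_identical(res$strength, "strong")
  y <- x + rnorm(40, 0, 2)
  expect_identical(correlate(x, y)$strength,
                   if (abs(cor(x, y)) < 0.3) "weak" else "moderate")
  expect_error(correlate(x, rep(1, 40)), "zero variance")
  expect_error(correlate(1:3, 2:4), "n >= 4")
})

test_that("bh_fdr implements the step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # returned in input order
  expect_equal(bh_fdr(c(0.04, 0.01)), c(0.04, 0.02))
  # properties against the stats::p.adjust oracle on random vectors
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("backward_ols eliminates noise, keeps signal, and reports diagnostics", {
  set.seed(41)
  n <- 120
  d <- data.frame(x = rnorm(n), nuisance = rnorm(n), z = rnorm(n))
  d$y <- 3 * d$x + rnorm(n, 0, 1e-4)
  fit <- backward_ols(d, "y", c("x", "nuisance", "z"))
  expect_identical(fit$coefficients$term, "x")
  expect_equal(fit$coefficients$beta, 3, tolerance = 1e-3)
  expect_setequal(fit$eliminated, c("nuisance", "z"))
  expect_true(all(fit$coefficients$vif < 10))
  expect_gt(fit$durbin_watson, 0)
  expect_lt(fit$model_p, 0.05)

  # p_remove = 1 returns the full model; standardized beta identity holds
  d$y2 <- 2 * d$x - 1.5 * d$z + rnorm(n, 0, 1)
  full <- backward_ols(d, "y2", c("x", "nuisance", "z"), p_remove = 1)
  expect_setequal(full$coefficients$term, c("x", "nuisance", "z"))
  for (k in seq_len(3)) {
    term <- full$coefficients$term[k]
    expect_equal(full$coefficients$beta_std[k],
                 full$coefficients$beta[k] * sd(d[[term]]) / sd(d$y2))
    expect_identical(sign(full$coefficients$beta_std[k]),
                     sign(full$coefficients$beta[k]))
  }
  # trace is reproducible for fixed input
  expect_identical(backward_ols(d, "y2", c("x", "nuisance", "z"))$eliminated,
                   backward_ols(d, "y2", c("x", "nuisance", "z"))$eliminated)

  # contract cases
  d$dup <- d$x
  expect_error(backward_ols(d, "y", c("x", "dup")), "rank-deficient")
  d$const <- 1
  expect_error(backward_ols(d, "y", c("x", "const")), "constant")
  expect_error(backward_ols(d[1:4, ], "y", c("x", "nuisance", "z")),
               "too small")
})
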