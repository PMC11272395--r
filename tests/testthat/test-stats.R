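test_that("pooled t statistic: hand value, sign convention, degenerate case", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  # pooled sp2 = 1, se = sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(two_sample_t(a, b), -3 / sqrt(2 / 3))
  expect_equal(two_sample_t(b, a), -two_sample_t(a, b))
  expect_equal(two_sample_t(a, a), 0)
  # cross-check against stats::t.test
  expect_equal(
    two_sample_t(a, b),
    unname(t.test(a, b, var.equal = TRUE)$statistic)
  )
  d <- two_sample_t(c(1, 1), c(1, 1))
  expect_identical(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("BH adjustment: hand case, edge cases, and the exhaustive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("Spearman correlation: hand ranking, invariance, errors", {
  # ranks of x = (1, 2.5, 2.5, 4), of y = (2, 1, 3.5, 3.5): Pearson = 0.5
  out <- spearman_cor(c(1, 2, 2, 4), c(3, 1, 4, 4))
  expect_equal(out$rho, 0.5)
  expect_identical(out$n, 4L)
  x <- c(0.3, 1.2, 0.7, 2.5, 1.9, 0.1)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # monotone transforms of either variable change nothing
  y <- c(2, 9, 4, 1, 7, 5)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(log(x), y^3)$rho)
  # p matches the t-approximation and cor.test's estimate (no ties)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman_cor(x, y)$rho, unname(ct$estimate))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "3 complete")
})

test_that("permutation test: reproducibility, labels and minimum attainable p", {
  set.seed(1)
  a <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("u", 1:5)))
  b <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("u", 1:5)))
  r1 <- mass_permutation_test(a, b, n_perm = 500, seed = 42)
  r2 <- mass_permutation_test(a, b, n_perm = 500, seed = 42)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$unit, paste0("u", 1:5))
  expect_true(all(r1$p > 0 & r1$p <= 1))
  expect_true(all(r1$p_fdr >= r1$p))
  # a 3-pooled-SD shift is never matched by any permutation
  set.seed(2)
  a2 <- cbind(a, planted = rnorm(20, 3, 1))
  b2 <- cbind(b, planted = rnorm(20, 0, 1))
  colnames(a2)[6] <- colnames(b2)[6] <- "planted"
  res <- mass_permutation_test(a2, b2, n_perm = 5000, seed = 7)
  expect_equal(res$p[res$unit == "planted"], 1 / 5001)
  expect_true(res$significant[res$unit == "planted"])
})

test_that("identical groups and degenerate units give p = 1", {
  x <- matrix(rnorm(10 * 3), 10, 3)
  res <- mass_permutation_test(x, x, n_perm = 200, seed = 1)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$p_fdr == 1))
  # an all-equal unit is flagged degenerate with p = 1
  a <- cbind(matrix(rnorm(12), 6, 2), flat = rep(2, 6))
  b <- cbind(matrix(rnorm(12), 6, 2), flat = rep(2, 6))
  res2 <- mass_permutation_test(a, b, n_perm = 200, seed = 3)
  expect_true(res2$degenerate[3])
  expect_equal(res2$p[3], 1)
  expect_warning(mass_permutation_test(a, b, n_perm = 50, seed = 1), "coarse")
})

test_that("subset of units reproduces the shared permutation stream exactly", {
  set.seed(9)
  a <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("u", 1:8)))
  b <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("u", 1:8)))
  full <- mass_permutation_test(a, b, n_perm = 300, seed = 11)
  sub <- mass_permutation_test(
    a[, 3:5], b[, 3:5],
    n_perm = 300, seed = 11
  )
  expect_identical(sub$p, full$p[3:5])
  expect_identical(sub$t, full$t[3:5])
})

test_that("node-wise covariate correlation flags the planted ROI", {
  des <- cohort_design(n_per_group = c(30, 30), covariate_specs = list(), seed = 5)
  coh <- gen_cohort(des)
  tab <- coh$subjects
  m <- coh$exponents
  for (j in seq_len(ncol(m))) tab[[paste0(colnames(m)[j], "_exp")]] <- m[, j]
  # covariate = exact copy of one ROI's exponent: rho = 1, survives FDR
  tab$shadow <- m[, "lh_cuneus"]
  res <- roi_covariate_correlation(tab, "shadow")
  expect_equal(res$rho[res$unit == "lh_cuneus"], 1)
  expect_true(res$significant[res$unit == "lh_cuneus"])
  # missing covariate values are pairwise-deleted and n is reported
  tab$shadow[1:5] <- NA
  res2 <- roi_covariate_correlation(tab, "shadow")
  expect_true(all(res2$n == 55))
  expect_error(roi_covariate_correlation(tab, "nope"), "available columns")
})

test_that("planted monotone covariate couplings are recovered after FDR", {
  rois <- dk_labels()[11:15]
  hits <- vapply(1:10, function(s) {
    des <- cohort_design(
      n_per_group = c(34, 33),
      covariate_specs = list(
        covariate_spec("cv", rois = rois, slope = 1, noise_sd = 0.089)
      ),
      subject_sd = 0.1, seed = 300 + s
    )
    coh <- gen_cohort(des)
    tab <- coh$subjects
    m <- coh$exponents
    for (j in seq_len(ncol(m))) tab[[paste0(colnames(m)[j], "_exp")]] <- m[, j]
    res <- roi_covariate_correlation(tab, "cv")
    sum(res$significant[res$unit %in% rois]) >= 4
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("gene-map correlation validates regions and finds an exact match", {
  expr <- matrix(runif(12), 6, 2, dimnames = list(paste0("r", 1:6), c("gA", "gB")))
  map <- setNames(as.numeric(expr[, 1]), rownames(expr))
  res <- gene_map_correlation(map, expr)
  expect_equal(res$rho[res$unit == "gA"], 1)
  bad_map <- setNames(runif(6), c(paste0("r", 1:5), "elsewhere"))
  expect_error(gene_map_correlation(bad_map, expr), "region mismatch")
})

test_that("OLS partial F tests match the squared t of the full fit", {
  set.seed(12)
  n <- 67
  d <- data.frame(asms = rpois(n, 2), memory = rnorm(n, 39, 9.75))
  d$exponent <- 1.5 + 0.05 * d$asms - 0.004 * d$memory + rnorm(n, 0, 0.1)
  res <- ols_f_tests(d, "exponent", c("asms", "memory", "asms:memory"))
  expect_identical(res$term, c("asms", "memory", "asms:memory"))
  full <- lm(exponent ~ asms * memory, d)
  tt <- summary(full)$coefficients[-1, "t value"]
  expect_equal(res$F, unname(tt^2), tolerance = 1e-8)
  # the interaction (last term) also matches drop1's F
  d1 <- drop1(full, test = "F")
  expect_equal(res$F[3], d1["asms:memory", "F value"])
  expect_equal(attr(res, "n"), n)
})

test_that("rank-deficient designs fail loudly, naming the collinear columns", {
  d <- data.frame(y = rnorm(20), x1 = rnorm(20))
  d$x2 <- d$x1 # duplicated predictor
  expect_error(ols_f_tests(d, "y", c("x1", "x2")), "collinear.*x2")
})

test_that("a planted main effect is detected with high power at n = 67", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 67
    d <- data.frame(asms = rpois(n, 2), memory = rnorm(n))
    # 1-SD main effect of medication count on the response
    d$exponent <- scale(d$asms)[, 1] + rnorm(n, 0, 1)
    res <- ols_f_tests(d, "exponent", c("asms", "memory", "asms:memory"))
    res$p[res$term == "asms"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
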