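#' Two-sample t statistic
#'
#' Pooled-variance (Student) two-sample t by default, with the sign
#' convention `mean(a) - mean(b)`. A variance-unpooled (Welch) variant is
#' available but off by default, matching the classical choice in the
#' mass-univariate permutation literature. A zero pooled variance yields
#' `t = 0` with a `"degenerate"` attribute.
#'
#' @param a,b Numeric vectors (each of length >= 2, finite).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return The t statistic (numeric scalar).
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("inputs must be finite")
  n1 <- length(a)
  n2 <- length(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(var(a) / n1 + var(b) / n2)
  }
  if (se == 0) {
    return(structure(0, degenerate = TRUE))
  }
  (mean(a) - mean(b)) / se
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector: monotone,
#' capped at 1, input order restored. Missing values are excluded from the
#' adjustment (and returned as `NA`).
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) {
    return(numeric(0))
  }
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

# vectorized column-wise pooled t for a permutation stream
col_t_stats <- function(x, x2, in1, n1, n2, var_equal = TRUE) {
  s1 <- colSums(x[in1, , drop = FALSE])
  ss1 <- colSums(x2[in1, , drop = FALSE])
  s2 <- colSums(x) - s1
  ss2 <- colSums(x2) - ss1
  m1 <- s1 / n1
  m2 <- s2 / n2
  if (var_equal) {
    sp2 <- (ss1 - n1 * m1^2 + ss2 - n2 * m2^2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- (ss1 - n1 * m1^2) / ((n1 - 1) * n1) + (ss2 - n2 * m2^2) / ((n2 - 1) * n2)
  }
  se2 <- pmax(se2, 0)
  t <- (m1 - m2) / sqrt(se2)
  t[se2 == 0] <- 0
  t
}

#' Mass-univariate permutation t-test with FDR control
#'
#' Computes a per-unit (per-ROI or per-gene) two-sample t statistic and
#' builds its null distribution by permuting the group labels: one label
#' permutation per iteration is applied to *all* units simultaneously
#' (shared permutation stream), preserving the spatial dependence of the
#' null. The two-tailed empirical p-value uses the `+1 / (m + 1)` correction,
#' `p = (#\{|t_perm| >= |t_obs|\} + 1) / (n_perm + 1)`, so p is never 0.
#' Benjamini-Hochberg FDR adjustment is applied across units.
#'
#' @param a,b Subjects x units numeric matrices for the two groups (matching
#'   columns; column names are the unit labels).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutation stream; identical seeds give
#'   identical empirical p-values to the last digit.
#' @param var_equal Pool variances in the t statistic (default `TRUE`).
#' @param alpha Significance level for the FDR flag (default 0.05).
#' @return data.frame of class `mass_test_result`: `unit`, `t`, `p`,
#'   `p_fdr`, `significant`, `degenerate`; `n_perm`, `seed` and group sizes
#'   in attributes.
#' @export
mass_permutation_test <- function(a, b, n_perm = 5000, seed = NULL,
                                  var_equal = TRUE, alpha = 0.05) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("a and b must have the same units (columns)")
  if (!is.null(colnames(a)) && !is.null(colnames(b)) &&
    !identical(colnames(a), colnames(b))) {
    stop("a and b must have identical column (unit) names")
  }
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse empirical p")
  n1 <- nrow(a)
  n2 <- nrow(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  x <- rbind(a, b)
  if (!all(is.finite(x))) stop("non-finite values in the data")
  x2 <- x * x
  n <- n1 + n2
  in1_obs <- rep(c(TRUE, FALSE), c(n1, n2))
  t_obs <- col_t_stats(x, x2, in1_obs, n1, n2, var_equal)
  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- numeric(ncol(x))
  abs_obs <- abs(t_obs)
  for (i in seq_len(n_perm)) {
    in1 <- logical(n)
    in1[sample.int(n, n1)] <- TRUE
    tp <- col_t_stats(x, x2, in1, n1, n2, var_equal)
    exceed <- exceed + (abs(tp) >= abs_obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  degenerate <- apply(x, 2, function(v) all(v == v[1]))
  p_fdr <- bh_fdr(p)
  units <- colnames(x)
  if (is.null(units)) units <- sprintf("unit_%03d", seq_len(ncol(x)))
  structure(
    data.frame(
      unit = units, t = t_obs, p = p, p_fdr = p_fdr,
      significant = p_fdr < alpha, degenerate = degenerate,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    n_perm = n_perm, seed = seed, n_groups = c(n1, n2), alpha = alpha,
    class = c("mass_test_result", "data.frame")
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average-rank ties; two-sided p via the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Incomplete pairs are removed.
#'
#' @param x,y Numeric vectors.
#' @param xname,yname Variable names used in error messages.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, xname = deparse(substitute(x)),
                         yname = deparse(substitute(y))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete finite pairs")
  if (sd(x) == 0) stop(sprintf("'%s' is constant; Spearman correlation undefined", xname))
  if (sd(y) == 0) stop(sprintf("'%s' is constant; Spearman correlation undefined", yname))
  rho <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n)
}

#' Node-wise covariate correlation across ROIs
#'
#' Spearman correlation between a subject-level covariate and each ROI's
#' exponent (or offset) across subjects, with BH-FDR adjustment across the
#' ROI set. Missing covariate values are pairwise-deleted; the per-ROI n is
#' reported. ROIs where the correlation is undefined (fewer than 3 pairs or
#' a constant variable) get `NA` with a log entry in `attr(, "log")`.
#'
#' @param table An `exponent_table` (see [extract_exponent_table()]) or any
#'   data.frame with `<roi>_exp` / `<roi>_off` columns plus the covariate.
#' @param covariate Covariate column name.
#' @param measure `"exponent"` or `"offset"`.
#' @param alpha Significance level for the FDR flag.
#' @return data.frame of class `mass_test_result`: `unit`, `rho`, `p`,
#'   `p_fdr`, `significant`, `n`.
#' @export
roi_covariate_correlation <- function(table, covariate,
                                      measure = c("exponent", "offset"),
                                      alpha = 0.05) {
  measure <- match.arg(measure)
  if (!covariate %in% names(table)) {
    stop(sprintf(
      "covariate '%s' not found; available columns: %s",
      covariate, paste(names(table), collapse = ", ")
    ))
  }
  m <- roi_measure_matrix(table, measure)
  cv <- table[[covariate]]
  if (mean(is.na(cv)) > 0.5) {
    warning(sprintf("more than 50%% of '%s' is missing", covariate))
  }
  log_entries <- character(0)
  res <- lapply(seq_len(ncol(m)), function(j) {
    out <- tryCatch(
      spearman_cor(m[, j], cv, xname = colnames(m)[j], yname = covariate),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      log_entries <<- c(log_entries, sprintf(
        "ROI %s: %s", colnames(m)[j], conditionMessage(out)
      ))
      list(rho = NA_real_, p = NA_real_, n = sum(is.finite(m[, j]) & is.finite(cv)))
    } else {
      out
    }
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  p_fdr <- bh_fdr(p)
  structure(
    data.frame(
      unit = colnames(m),
      rho = vapply(res, `[[`, numeric(1), "rho"),
      p = p, p_fdr = p_fdr,
      significant = !is.na(p_fdr) & p_fdr < alpha,
      n = vapply(res, `[[`, numeric(1), "n"),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    covariate = covariate, measure = measure, alpha = alpha,
    log = log_entries,
    class = c("mass_test_result", "data.frame")
  )
}

#' Gene-map correlation with a regional exponent map
#'
#' Spearman correlation, across atlas regions, between each gene's
#' expression column and a regional mean-exponent map, with BH-FDR
#' adjustment across the gene set.
#'
#' @param exponent_map Named numeric vector of per-region exponent values
#'   (e.g. the patient-group mean per ROI).
#' @param expr Regions x genes matrix from [build_expression_matrix()]
#'   (rownames = regions).
#' @param alpha Significance level for the FDR flag.
#' @return data.frame of class `mass_test_result`: `unit` (gene), `rho`,
#'   `p`, `p_fdr`, `significant`, `n`.
#' @export
gene_map_correlation <- function(exponent_map, expr, alpha = 0.05) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.null(names(exponent_map))) {
    if (length(exponent_map) != nrow(expr)) {
      stop("unnamed exponent_map must match the expression matrix rows")
    }
    names(exponent_map) <- rownames(expr)
  }
  extra_map <- setdiff(names(exponent_map), rownames(expr))
  extra_expr <- setdiff(rownames(expr), names(exponent_map))
  if (length(extra_map) || length(extra_expr)) {
    stop(sprintf(
      "region mismatch between exponent map and expression matrix;\n  only in map: %s\n  only in expression: %s",
      if (length(extra_map)) paste(extra_map, collapse = ", ") else "(none)",
      if (length(extra_expr)) paste(extra_expr, collapse = ", ") else "(none)"
    ))
  }
  if (ncol(expr) < 1L) stop("expression matrix has no genes")
  map <- exponent_map[rownames(expr)]
  res <- lapply(seq_len(ncol(expr)), function(j) {
    spearman_cor(map, expr[, j], xname = "exponent_map", yname = colnames(expr)[j])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  p_fdr <- bh_fdr(p)
  structure(
    data.frame(
      unit = colnames(expr),
      rho = vapply(res, `[[`, numeric(1), "rho"),
      p = p, p_fdr = p_fdr,
      significant = !is.na(p_fdr) & p_fdr < alpha,
      n = vapply(res, `[[`, numeric(1), "n"),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    alpha = alpha,
    class = c("mass_test_result", "data.frame")
  )
}

#' Multiple linear regression with per-term partial F tests
#'
#' Ordinary least squares with listwise deletion, reporting for every term
#' (including interactions) the partial F comparing the full model against
#' the model with that term's columns removed (all other terms retained),
#' i.e. marginal (Type III-style) tests — appropriate for the two E/I
#' models: `exponent ~ asms + memory + asms:memory` and
#' `memory ~ exponent + asms + exponent:asms`.
#'
#' @param data data.frame holding response and predictors.
#' @param response Response column name.
#' @param terms Character vector of term labels (use `"a:b"` for an
#'   interaction).
#' @return data.frame of class `regression_result` with `term`, `df`, `F`,
#'   `p`; coefficients, n and R^2 in attributes.
#' @export
ols_f_tests <- function(data, response, terms) {
  stopifnot(response %in% names(data), length(terms) >= 1L)
  form <- stats::reformulate(terms, response = response)
  mf <- stats::model.frame(form, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(form, mf)
  n <- nrow(mm)
  if (n <= ncol(mm)) stop("too few complete observations for the model")
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[seq(qrm$rank + 1L, ncol(mm))]]
    stop(sprintf(
      "rank-deficient design; collinear term column(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  fit_full <- lm.fit(mm, y)
  rss_full <- sum(fit_full$residuals^2)
  df_res <- n - ncol(mm)
  assign <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  rows <- lapply(seq_along(labels), function(k) {
    keep <- assign != k
    fit_r <- lm.fit(mm[, keep, drop = FALSE], y)
    rss_r <- sum(fit_r$residuals^2)
    df_t <- sum(!keep)
    fval <- ((rss_r - rss_full) / df_t) / (rss_full / df_res)
    fval <- max(fval, 0)
    data.frame(
      term = labels[k], df = df_t, F = fval,
      p = pf(fval, df_t, df_res, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out,
    coefficients = fit_full$coefficients, n = n,
    r_squared = 1 - rss_full / sum((y - mean(y))^2),
    df_residual = df_res,
    class = c("regression_result", "data.frame")
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS partial F tests (n = %d, R^2 = %.3f)\n",
    attr(x, "n"), attr(x, "r_squared")
  ))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Split an exponent table into per-group measure matrices
#'
#' Convenience for feeding [mass_permutation_test()]: returns the subjects x
#' ROIs matrix of the requested measure for each declared group.
#'
#' @param table An `exponent_table` with a `group` column.
#' @param groups Two group labels (first = case group).
#' @param measure `"exponent"` or `"offset"`.
#' @return List of two matrices, named by group.
#' @export
split_groups <- function(table, groups, measure = c("exponent", "offset")) {
  measure <- match.arg(measure)
  stopifnot("group" %in% names(table), length(groups) == 2L)
  missing_g <- setdiff(groups, unique(table$group))
  if (length(missing_g)) {
    stop(sprintf("group(s) not present in table: %s", paste(missing_g, collapse = ", ")))
  }
  m <- roi_measure_matrix(table, measure)
  setNames(
    lapply(groups, function(g) m[table$group == g, , drop = FALSE]),
    groups
  )
}
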