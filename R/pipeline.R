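#' Run configuration for end-to-end analyses
#'
#' A single validated configuration object drives the orchestrated runs:
#' every stochastic stage takes its stream from `seed`, parameters are
#' echoed into the run report, and the configuration hash recorded in every
#' output changes whenever any parameter changes.
#'
#' @param seed Integer seed (mandatory: every stochastic stage derives from
#'   it).
#' @param groups Two group labels, case group first.
#' @param measures Measures to analyze: subset of `c("exponent", "offset")`.
#' @param n_perm Permutations for group contrasts (default 5000).
#' @param covariates Covariate column names for the correlation suite.
#' @param models List of regression model specs, each
#'   `list(response = ..., terms = c(...))`.
#' @param hyperparams A [fit_hyperparams()].
#' @param alpha Significance level (default 0.05).
#' @param gene_map_group Group whose mean ROI exponent map is correlated
#'   with gene expression (default the case group).
#' @param table_path,expr_path Optional TSV paths read at run time when the
#'   corresponding object is not passed directly.
#' @param out_dir Optional output directory; when set, result tables are
#'   written as TSV (+ JSON metadata).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, groups = c("TLE", "HC"),
                       measures = "exponent", n_perm = 5000,
                       covariates = character(0), models = list(),
                       hyperparams = fit_hyperparams(), alpha = 0.05,
                       gene_map_group = groups[1],
                       table_path = NULL, expr_path = NULL, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for any stochastic stage")
  }
  stopifnot(length(groups) == 2L, all(measures %in% c("exponent", "offset")))
  for (p in c(table_path, expr_path)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("path does not exist: %s", p))
  }
  # canonical types so a JSON round trip preserves the config hash
  models <- lapply(models, function(m) {
    list(response = as.character(m$response), terms = as.character(m$terms))
  })
  structure(
    list(
      seed = as.integer(seed), groups = as.character(groups),
      measures = as.character(measures),
      n_perm = as.integer(n_perm), covariates = as.character(covariates),
      models = models,
      hyperparams = hyperparams, alpha = as.numeric(alpha),
      gene_map_group = as.character(gene_map_group),
      table_path = table_path, expr_path = expr_path, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' MD5 hash of a run configuration
#'
#' @param config A [run_config()].
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON path.
#' @param config A [run_config()].
#' @return A [run_config()] (read) or the path (write).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- if (!is.null(x$hyperparams)) {
    h <- x$hyperparams
    h$max_n_peaks <- as.numeric(h$max_n_peaks) # "Inf" comes back as string
    do.call(fit_hyperparams, h)
  } else {
    fit_hyperparams()
  }
  models <- lapply(x$models, function(m) list(response = m$response, terms = m$terms))
  run_config(
    seed = x$seed,
    groups = x$groups %||% c("TLE", "HC"),
    measures = x$measures %||% "exponent",
    n_perm = x$n_perm %||% 5000,
    covariates = x$covariates %||% character(0),
    models = models,
    hyperparams = hp,
    alpha = x$alpha %||% 0.05,
    gene_map_group = x$gene_map_group %||% (x$groups %||% c("TLE", "HC"))[1],
    table_path = x$table_path, expr_path = x$expr_path, out_dir = x$out_dir
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$hyperparams <- unclass(x$hyperparams)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(report, stage, ...) {
  entry <- sprintf("[%s] %s", stage, sprintf(...))
  message(entry)
  report$log <- c(report$log, entry)
  report
}

new_run_report <- function(config) {
  list(
    config = config, config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("apexei")),
    results = list(), qc = list(), summary = list(), log = character(0)
  )
}

resolve_table <- function(config, table) {
  if (is.null(table)) {
    if (is.null(config$table_path)) stop("no exponent table supplied (object or table_path)")
    table <- read_exponent_table(config$table_path)
  }
  table
}

#' Run the group-comparison stage
#'
#' Contrasts the case group against controls for every configured measure
#' (exponent and/or offset) with the mass-univariate permutation t-test and
#' BH-FDR across ROIs, and summarizes max |t| and the FDR-significant ROI
#' count. Result tables are written as TSV when `config$out_dir` is set.
#'
#' @param config A [run_config()].
#' @param table An `exponent_table` (with `group` column); read from
#'   `config$table_path` when omitted.
#' @return A run report (list of class `run_report`): per-stage parameter
#'   echo, results, QC counts, config hash.
#' @export
run_group_comparison <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  table <- resolve_table(config, table)
  report <- new_run_report(config)
  counts <- table(table$group)
  for (g in config$groups) {
    if (is.na(counts[g]) || counts[g] < 2L) {
      stop(sprintf("group '%s' has fewer than 2 subjects", g))
    }
  }
  report <- log_stage(
    report, "group_comparison", "groups %s (n = %s), %d permutations, seed %d",
    paste(config$groups, collapse = " vs "),
    paste(counts[config$groups], collapse = " + "),
    config$n_perm, config$seed
  )
  for (measure in config$measures) {
    gm <- split_groups(table, config$groups, measure)
    res <- mass_permutation_test(
      gm[[1]], gm[[2]],
      n_perm = config$n_perm,
      seed = config$seed, alpha = config$alpha
    )
    key <- paste0("group_", measure)
    report$results[[key]] <- res
    report$summary[[key]] <- list(
      t_max = max(abs(res$t)),
      n_significant = sum(res$significant),
      n_units = nrow(res)
    )
    report <- log_stage(
      report, "group_comparison",
      "%s: max |t| = %.3f, %d/%d ROIs FDR-significant at alpha = %g",
      measure, max(abs(res$t)), sum(res$significant), nrow(res), config$alpha
    )
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
      out <- file.path(config$out_dir, sprintf("group_test_%s.tsv", measure))
      write_mass_result(res, out)
      report <- log_stage(report, "group_comparison", "wrote %s", out)
    }
  }
  class(report) <- "run_report"
  report
}

#' Run the correlation and regression suite
#'
#' Node-wise Spearman correlation of each configured covariate with the
#' per-ROI exponent, gene-map correlation against the case-group mean
#' exponent map (when an expression matrix is available), and the
#' configured multiple-regression models — consolidated into one report.
#'
#' @param config A [run_config()].
#' @param table An `exponent_table`; read from `config$table_path` when
#'   omitted.
#' @param expr Optional regions x genes matrix (see
#'   [build_expression_matrix()]); read from `config$expr_path` when omitted
#'   and configured.
#' @return A run report (list of class `run_report`).
#' @export
run_correlation_suite <- function(config, table = NULL, expr = NULL) {
  stopifnot(inherits(config, "run_config"))
  table <- resolve_table(config, table)
  if (is.null(expr) && !is.null(config$expr_path)) {
    expr <- read_gene_matrix(config$expr_path)
  }
  report <- new_run_report(config)
  r2 <- attr(table, "r_squared")
  if (!is.null(r2)) {
    report$qc$fit_r_squared <- summary(as.numeric(r2))
    report$qc$n_failed_fits <- sum(is.na(r2))
  }
  report <- log_stage(
    report, "correlation_suite", "%d subjects, %d covariate(s), genes: %s",
    nrow(table), length(config$covariates),
    if (is.null(expr)) "none" else ncol(expr)
  )

  for (cv in config$covariates) {
    res <- roi_covariate_correlation(table, cv, alpha = config$alpha)
    key <- paste0("covariate_", cv)
    report$results[[key]] <- res
    report$summary[[key]] <- list(
      rho_max = res$rho[which.max(abs(res$rho))],
      n_significant = sum(res$significant)
    )
    report <- log_stage(
      report, "correlation_suite",
      "covariate %s: max |rho| = %.3f, %d ROIs FDR-significant",
      cv, max(abs(res$rho), na.rm = TRUE), sum(res$significant)
    )
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
      write_mass_result(res, file.path(config$out_dir, sprintf("corr_%s.tsv", cv)))
    }
  }

  if (!is.null(expr)) {
    sel <- table$group == config$gene_map_group
    if (!any(sel)) stop(sprintf("no subjects in gene_map_group '%s'", config$gene_map_group))
    map <- colMeans(roi_measure_matrix(table[sel, , drop = FALSE], "exponent"))
    res <- gene_map_correlation(map, expr, alpha = config$alpha)
    report$results$gene_map <- res
    report$summary$gene_map <- list(
      rho_max = res$rho[which.max(abs(res$rho))],
      n_significant = sum(res$significant)
    )
    report <- log_stage(
      report, "correlation_suite",
      "gene map (%s mean exponent): %d/%d genes FDR-significant",
      config$gene_map_group, sum(res$significant), nrow(res)
    )
    if (!is.null(config$out_dir)) {
      write_mass_result(res, file.path(config$out_dir, "gene_corr.tsv"))
    }
  }

  for (mi in seq_along(config$models)) {
    m <- config$models[[mi]]
    res <- ols_f_tests(table, m$response, m$terms)
    key <- sprintf("model_%d_%s", mi, m$response)
    report$results[[key]] <- res
    report <- log_stage(
      report, "correlation_suite", "model %s ~ %s: F = %s",
      m$response, paste(m$terms, collapse = " + "),
      paste(sprintf("%s %.3f (p=%.4f)", res$term, res$F, res$p), collapse = ", ")
    )
    if (!is.null(config$out_dir)) {
      write_tsv(as.data.frame(res), file.path(config$out_dir, paste0(key, ".tsv")))
    }
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> config %s, %d result table(s)\n",
    substr(x$config_hash, 1, 8), length(x$results)
  ))
  for (entry in x$log) cat(" ", entry, "\n")
  invisible(x)
}
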