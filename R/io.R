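#' Read a TSV file with strict row validation
#'
#' Fails fast on ragged rows, naming the first offending row, before any
#' parsing: malformed tables never propagate silently into the pipeline.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf(
      "ragged TSV '%s': row %d has %d fields, expected %d",
      path, bad, nf[bad], nf[1]
    ))
  }
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(x, path) {
  write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Write / read an exponent table as TSV
#'
#' Columns: `subject_id`, group and covariates, then one `<roi>_exp` and one
#' `<roi>_off` column per ROI.
#'
#' @param table An `exponent_table`.
#' @param path Output TSV path.
#' @return The path (write) or the table (read), invisibly for write.
#' @export
write_exponent_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_exponent_table
#' @export
read_exponent_table <- function(path) {
  df <- read_tsv_checked(path)
  exp_cols <- grep("_exp$", names(df), value = TRUE)
  structure(df,
    roi_labels = sub("_exp$", "", exp_cols),
    class = c("exponent_table", "data.frame")
  )
}

#' Write / read one subject's ROI time series as TSV
#'
#' The data file holds one row per ROI (first column `roi`, then one column
#' per sample); a JSON sidecar (`<file>.json`) carries `subject_id` and
#' `fs`.
#'
#' @param ts A [roi_ts].
#' @param dir Output directory (write) — the file is `<subject_id>.tsv`.
#' @param path Path of the data TSV (read).
#' @return Written TSV path, or the [roi_ts] on read.
#' @export
write_roi_ts <- function(ts, dir) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(ts$subject_id, ".tsv"))
  df <- data.frame(roi = ts$roi_labels, ts$data, check.names = FALSE)
  colnames(df) <- c("roi", sprintf("s%06d", seq_len(ncol(ts$data))))
  write_tsv(df, path)
  jsonlite::write_json(
    list(subject_id = ts$subject_id, fs = ts$fs),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read_tsv_checked(path)
  roi_ts(
    subject_id = meta$subject_id,
    data = as.matrix(df[, -1, drop = FALSE]),
    roi_labels = df$roi, fs = meta$fs
  )
}

#' Write a mass test result as TSV plus JSON metadata
#'
#' @param res A `mass_test_result`.
#' @param path Output TSV path; metadata (n_perm, seed, alpha, group sizes)
#'   goes to `<path>.json`.
#' @return The TSV path, invisibly.
#' @export
write_mass_result <- function(res, path) {
  write_tsv(as.data.frame(res), path)
  meta <- list(
    n_perm = attr(res, "n_perm"), seed = attr(res, "seed"),
    alpha = attr(res, "alpha"), n_groups = attr(res, "n_groups"),
    covariate = attr(res, "covariate"), measure = attr(res, "measure")
  )
  jsonlite::write_json(
    meta[!vapply(meta, is.null, TRUE)], paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read a regions x genes expression matrix as TSV
#'
#' @param expr Matrix from [build_expression_matrix()].
#' @param path TSV path (first column `region_id`); per-gene probe
#'   provenance goes to `<path>.json`.
#' @return The path, or the matrix on read.
#' @export
write_gene_matrix <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr), expr, check.names = FALSE)
  write_tsv(df, path)
  prov <- attr(expr, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(as.list(prov), paste0(path, ".json"),
      auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(path) {
  df <- read_tsv_checked(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  storage.mode(m) <- "double"
  prov_path <- paste0(path, ".json")
  if (file.exists(prov_path)) {
    attr(m, "provenance") <- unlist(jsonlite::read_json(prov_path, simplifyVector = TRUE))
  }
  m
}

#' Write a cohort's ground-truth sidecar as JSON
#'
#' @param cohort An `ei_cohort`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "ei_cohort"))
  d <- cohort$truth$design
  jsonlite::write_json(
    list(
      seed = d$seed, groups = d$groups, n_per_group = d$n_per_group,
      roi_labels = d$roi_labels,
      baseline_exponent_map = d$baseline_exponent_map,
      group_effect_map = d$group_effect_map,
      baseline_offset_map = d$baseline_offset_map,
      offset_effect_map = d$offset_effect_map,
      subject_sd = d$subject_sd, roi_noise_sd = d$roi_noise_sd,
      exponents = cohort$truth$exponents,
      offsets = cohort$truth$offsets
    ),
    path,
    digits = NA
  )
  invisible(path)
}
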