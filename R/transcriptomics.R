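#' Filter probes by expression intensity relative to background
#'
#' A probe is discarded when its expression is below background (the
#' `above_background` flag is `FALSE`) in 50% or more of its samples;
#' equivalently, it is retained iff the below-background fraction is
#' strictly less than 0.5. A probe below background in exactly half of its
#' samples is discarded.
#'
#' @param panel Probe-level data.frame with at least `probe_id` and a logical
#'   `above_background` column.
#' @return Character vector of retained probe ids (sorted).
#' @export
filter_probes_by_intensity <- function(panel) {
  stopifnot(all(c("probe_id", "above_background") %in% names(panel)))
  if (any(is.na(panel$above_background))) {
    stop("above_background must be defined for every sample")
  }
  frac_below <- tapply(!panel$above_background, panel$probe_id, mean)
  sort(names(frac_below)[frac_below < 0.5])
}

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Differential stability of a probe across donors
#'
#' The mean, over all `N * (N - 1) / 2` donor pairs, of the Spearman rank
#' correlation between the two donors' regional expression profiles of the
#' probe, restricted to the regions both donors cover. Regional profiles are
#' the mean expression over the donor's tissue samples in each region.
#' Donor pairs with fewer than 3 common regions, or with a constant profile
#' (undefined rank correlation), are excluded with a warning.
#'
#' @param panel Probe-level data.frame (`donor_id`, `probe_id`, `region_id`,
#'   `expression`).
#' @param probe_id The probe to evaluate.
#' @return Differential stability in \[-1, 1\].
#' @export
differential_stability <- function(panel, probe_id) {
  stopifnot(all(c("donor_id", "probe_id", "region_id", "expression") %in% names(panel)))
  sub <- panel[panel$probe_id == probe_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("probe '%s' has zero samples", probe_id))
  if (any(!is.finite(sub$expression))) stop("expression must be finite")
  donors <- sort(unique(sub$donor_id))
  if (length(donors) < 2L) {
    stop(sprintf("probe '%s' measured in fewer than 2 donors", probe_id))
  }
  profiles <- lapply(donors, function(d) {
    rows <- sub[sub$donor_id == d, ]
    tapply(rows$expression, rows$region_id, mean)
  })
  rhos <- c()
  for (i in seq_len(length(donors) - 1L)) {
    for (j in seq(i + 1L, length(donors))) {
      common <- intersect(names(profiles[[i]]), names(profiles[[j]]))
      if (length(common) < 3L) {
        warning(sprintf(
          "donor pair (%s, %s) shares fewer than 3 regions for probe '%s'; excluded",
          donors[i], donors[j], probe_id
        ))
        next
      }
      r <- spearman_rho(profiles[[i]][common], profiles[[j]][common])
      if (is.na(r)) {
        warning(sprintf(
          "constant regional profile in donor pair (%s, %s) for probe '%s'; pair excluded",
          donors[i], donors[j], probe_id
        ))
        next
      }
      rhos <- c(rhos, r)
    }
  }
  if (length(rhos) == 0L) {
    stop(sprintf("no valid donor pairs for probe '%s'", probe_id))
  }
  mean(rhos)
}

#' Select one probe per gene by differential stability
#'
#' Among the intensity-retained probes of each gene, selects the probe with
#' the most consistent pattern of regional variation across donors (largest
#' [differential_stability()]). Single-probe genes are selected trivially;
#' ties are broken by lexicographically smallest probe id (deterministic
#' across platforms). Genes with no retained probe are dropped with a
#' message.
#'
#' @param panel Probe-level data.frame (`donor_id`, `probe_id`, `gene`,
#'   `region_id`, `expression`, `above_background`).
#' @param retained Retained probe ids; default computed by
#'   [filter_probes_by_intensity()].
#' @return Named character vector: gene -> selected probe id.
#' @export
select_probe_per_gene <- function(panel, retained = NULL) {
  stopifnot(all(c("probe_id", "gene") %in% names(panel)))
  if (is.null(retained)) retained <- filter_probes_by_intensity(panel)
  probe_gene <- unique(panel[, c("probe_id", "gene")])
  genes <- sort(unique(panel$gene))
  out <- character(0)
  dropped <- character(0)
  for (g in genes) {
    probes <- sort(intersect(probe_gene$probe_id[probe_gene$gene == g], retained))
    if (length(probes) == 0L) {
      dropped <- c(dropped, g)
      next
    }
    if (length(probes) == 1L) {
      out[g] <- probes
      next
    }
    ds <- vapply(probes, function(p) {
      suppressWarnings(tryCatch(
        differential_stability(panel, p),
        error = function(e) -Inf
      ))
    }, numeric(1))
    ds[is.na(ds)] <- -Inf
    # probes are sorted, so which.max resolves ties lexicographically
    out[g] <- probes[which.max(ds)]
  }
  if (length(dropped)) {
    message(sprintf(
      "%d gene(s) dropped (no intensity-retained probe): %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  out
}

#' Assign tissue samples to atlas regions by proximity
#'
#' Each sample is matched to the nearest region centroid within the same
#' hemisphere; matches farther than `max_dist_mm` (Euclidean distance,
#' default 2 mm) are discarded. The hemisphere constraint dominates
#' distance: an opposite-hemisphere centroid is never assigned, however
#' close.
#'
#' @param samples data.frame with `sample_id`, `hemisphere`, `x_mm`, `y_mm`,
#'   `z_mm` (one row per sample; duplicated sample ids are deduplicated).
#' @param centroids data.frame with `region_id`, `hemisphere`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @param max_dist_mm Assignment threshold in mm.
#' @return data.frame with `sample_id`, `region_id` (`NA` = discarded),
#'   `distance_mm`.
#' @export
assign_samples_to_regions <- function(samples, centroids, max_dist_mm = 2) {
  need <- c("sample_id", "hemisphere", "x_mm", "y_mm", "z_mm")
  stopifnot(all(need %in% names(samples)))
  stopifnot(all(c("region_id", "hemisphere", "x_mm", "y_mm", "z_mm") %in% names(centroids)))
  samples <- unique(samples[, need])
  if (any(is.na(samples$hemisphere))) stop("missing hemisphere label in samples")
  if (any(is.na(centroids$hemisphere))) stop("missing hemisphere label in centroids")
  if (!all(is.finite(as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])))) {
    stop("sample coordinates must be finite")
  }
  region <- rep(NA_character_, nrow(samples))
  dist_mm <- rep(NA_real_, nrow(samples))
  for (i in seq_len(nrow(samples))) {
    cand <- centroids[centroids$hemisphere == samples$hemisphere[i], ]
    if (nrow(cand) == 0L) next
    d <- sqrt((cand$x_mm - samples$x_mm[i])^2 +
      (cand$y_mm - samples$y_mm[i])^2 +
      (cand$z_mm - samples$z_mm[i])^2)
    j <- which.min(d)
    dist_mm[i] <- d[j]
    if (d[j] <= max_dist_mm) region[i] <- cand$region_id[j]
  }
  n_drop <- sum(is.na(region))
  if (n_drop > 0) {
    message(sprintf("%d sample(s) beyond %g mm of any same-hemisphere centroid; discarded", n_drop, max_dist_mm))
  }
  data.frame(
    sample_id = samples$sample_id, region_id = region,
    distance_mm = dist_mm, stringsAsFactors = FALSE
  )
}

#' Robust sigmoid normalization to the unit interval
#'
#' Outlier-resistant squashing of a value vector:
#' `x_norm = 1 / (1 + exp(-(x - median(x)) / IQR_x))`, followed by rescaling
#' to the unit interval, `(x_norm - min) / (max - min)`. `IQR_x` is by
#' default the *normalized* interquartile range `(Q75 - Q25) / 1.349`, which
#' estimates the standard deviation under normality (the plain interquartile
#' range is available via `iqr_scale = "raw"`). Quartiles use linear
#' interpolation (type 7). The map is strictly monotone and invariant under
#' positive affine transforms of the input. A degenerate input with zero IQR
#' yields all 0.5 with a warning.
#'
#' @param x Numeric vector (one tissue sample across genes, or one gene
#'   across regions).
#' @param iqr_scale `"normalized"` (divide the IQR by 1.349) or `"raw"`.
#' @param rescale Rescale the sigmoid output to attain 0 and 1 (default).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' robust_sigmoid_normalize(c(1, 2, 3, 4, 100))
robust_sigmoid_normalize <- function(x, iqr_scale = c("normalized", "raw"),
                                     rescale = TRUE) {
  iqr_scale <- match.arg(iqr_scale)
  stopifnot(is.numeric(x), all(is.finite(x)))
  med <- median(x)
  iqr <- quantile(x, 0.75, names = FALSE, type = 7) -
    quantile(x, 0.25, names = FALSE, type = 7)
  denom <- if (iqr_scale == "normalized") iqr / 1.349 else iqr
  if (denom == 0) {
    warning("zero interquartile range; returning 0.5 for all values")
    return(rep(0.5, length(x)))
  }
  xn <- 1 / (1 + exp(-(x - med) / denom))
  if (rescale) xn <- (xn - min(xn)) / (max(xn) - min(xn))
  xn
}

#' Build the regions x genes expression matrix
#'
#' Implements the donor-wise reduction of a probe-level panel to a single
#' regions x genes matrix on the unit interval: (1) restrict to the selected
#' probe of each gene; (2) map samples to regions (either a supplied
#' assignment from [assign_samples_to_regions()] or the panel's own
#' `region_id`); (3) per donor, normalize each tissue sample across genes
#' with the robust sigmoid, aggregate samples to regions by mean, then
#' normalize each gene across regions with the identical procedure; (4)
#' average the donor matrices elementwise over the donors covering each
#' region. Regions covered by no donor are `NA` rows, logged via a message.
#'
#' @param panel Probe-level data.frame (schema of [gen_probe_panel()]).
#' @param assignments Optional data.frame (`sample_id`, `region_id`) from
#'   [assign_samples_to_regions()]; rows with `NA` region are discarded.
#' @param selections Optional named gene -> probe map from
#'   [select_probe_per_gene()]; computed if omitted.
#' @param regions Region universe for the output rows (default: regions
#'   observed in the panel, sorted).
#' @param iqr_scale Passed to [robust_sigmoid_normalize()].
#' @return Numeric matrix regions x genes, entries in \[0, 1\] (or `NA`),
#'   with the per-gene selected probe in `attr(, "provenance")`.
#' @export
build_expression_matrix <- function(panel, assignments = NULL,
                                    selections = NULL, regions = NULL,
                                    iqr_scale = "normalized") {
  need <- c("donor_id", "sample_id", "probe_id", "gene", "expression")
  stopifnot(all(need %in% names(panel)))
  if (is.null(selections)) selections <- select_probe_per_gene(panel)
  if (length(selections) == 0L) stop("no genes with retained probes")
  sub <- panel[panel$probe_id %in% selections, , drop = FALSE]
  if (!is.null(assignments)) {
    m <- match(sub$sample_id, assignments$sample_id)
    sub$region_id <- assignments$region_id[m]
  } else if (!"region_id" %in% names(sub)) {
    stop("panel has no region_id column and no assignments were supplied")
  }
  sub <- sub[!is.na(sub$region_id), , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty panel after filtering and assignment")
  if (is.null(regions)) regions <- sort(unique(sub$region_id))
  genes <- names(selections)
  donors <- sort(unique(sub$donor_id))

  donor_mats <- lapply(donors, function(d) {
    ds <- sub[sub$donor_id == d, , drop = FALSE]
    samp_ids <- sort(unique(ds$sample_id))
    sm <- matrix(NA_real_, length(samp_ids), length(genes),
      dimnames = list(samp_ids, genes)
    )
    idx <- cbind(
      match(ds$sample_id, samp_ids),
      match(ds$gene, genes)
    )
    sm[idx] <- ds$expression
    # normalize each tissue sample across genes
    for (i in seq_len(nrow(sm))) {
      ok <- !is.na(sm[i, ])
      if (sum(ok) >= 2L) {
        sm[i, ok] <- robust_sigmoid_normalize(sm[i, ok], iqr_scale = iqr_scale)
      }
    }
    # aggregate samples to regions
    samp_region <- ds$region_id[match(samp_ids, ds$sample_id)]
    rm_ <- matrix(NA_real_, length(regions), length(genes),
      dimnames = list(regions, genes)
    )
    for (r in unique(samp_region)) {
      rows <- sm[samp_region == r, , drop = FALSE]
      rm_[r, ] <- colMeans(rows, na.rm = TRUE)
    }
    rm_[is.nan(rm_)] <- NA_real_
    # normalize each gene across the donor's covered regions
    for (j in seq_len(ncol(rm_))) {
      ok <- !is.na(rm_[, j])
      if (sum(ok) >= 2L) {
        rm_[ok, j] <- robust_sigmoid_normalize(rm_[ok, j], iqr_scale = iqr_scale)
      }
    }
    rm_
  })

  acc <- matrix(0, length(regions), length(genes), dimnames = list(regions, genes))
  cnt <- matrix(0L, length(regions), length(genes))
  for (dm in donor_mats) {
    ok <- !is.na(dm)
    acc[ok] <- acc[ok] + dm[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  uncovered <- rownames(out)[rowSums(cnt) == 0L]
  if (length(uncovered)) {
    message(sprintf(
      "%d region(s) with no donor coverage: %s",
      length(uncovered), paste(uncovered, collapse = ", ")
    ))
  }
  attr(out, "provenance") <- selections
  out
}
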