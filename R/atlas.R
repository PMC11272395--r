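#' Desikan-Killiany cortical ROI labels
#'
#' The 68 cortical regions of the Desikan-Killiany atlas (34 per hemisphere),
#' prefixed `lh_` / `rh_`. This is the parcellation on which all ROI-level
#' machinery in apexei operates.
#'
#' @return Character vector of length 68.
#' @export
#' @examples
#' head(dk_labels())
dk_labels <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
  )
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Default E/I-related gene panel
#'
#' A 22-gene panel of epilepsy-related genes involved in the regulation of
#' intra- and intercellular E/I balance: sodium and potassium channel
#' subunits, GABA-A and NMDA receptor subunits, and seizure-susceptibility
#' genes. This is a synthetic stand-in panel assembled for testing the
#' gene-map correlation machinery (the genes are real symbols, the selection
#' is this package's own); replace with your curated list for real analyses.
#'
#' @return Character vector of 22 HGNC gene symbols.
#' @export
epilepsy_gene_panel <- function() {
  c(
    "SCN1A", "SCN1B", "SCN2A", "SCN8A",
    "KCNA1", "KCNA2", "KCNQ2", "KCNQ3", "KCNT1",
    "GABRA1", "GABRB3", "GABRD", "GABRG2",
    "GRIN1", "GRIN2A", "GRIN2B",
    "GABBR1", "GABBR2",
    "PDYN", "DEPDC5", "CHRNA4", "HCN1"
  )
}

#' Synthetic region centroids for sample-to-region assignment
#'
#' Deterministic centroid coordinates (mm) for the 68 Desikan-Killiany ROIs,
#' laid out on a hemisphere-signed 3-D grid: left-hemisphere regions at
#' negative x, right at positive x, regions spaced 20 mm apart within a
#' hemisphere. These are synthetic coordinates for exercising and testing
#' [assign_samples_to_regions()]; they are not anatomical centroids.
#'
#' @param roi_labels Region labels; defaults to [dk_labels()]. Labels must be
#'   prefixed `lh_` or `rh_`.
#' @return data.frame with columns `region_id`, `hemisphere` ("L"/"R"),
#'   `x_mm`, `y_mm`, `z_mm`.
#' @export
dk_centroids <- function(roi_labels = dk_labels()) {
  hemi <- ifelse(startsWith(roi_labels, "lh_"), "L",
    ifelse(startsWith(roi_labels, "rh_"), "R", NA_character_)
  )
  if (anyNA(hemi)) {
    stop("roi_labels must be prefixed 'lh_' or 'rh_'")
  }
  idx <- stats::ave(seq_along(roi_labels), hemi, FUN = seq_along) - 1L
  # 20 mm grid: 5 columns (y) x 7 rows (z) per hemisphere, |x| = 40 or 60
  x <- ifelse(hemi == "L", -1, 1) * (40 + 20 * (idx %/% 35))
  y <- -40 + 20 * ((idx %% 35) %% 5)
  z <- -20 + 20 * ((idx %% 35) %/% 5)
  data.frame(
    region_id = roi_labels, hemisphere = hemi,
    x_mm = x, y_mm = y, z_mm = z,
    stringsAsFactors = FALSE
  )
}
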