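#' Specification of a synthetic aperiodic EEG-like signal
#'
#' Describes a stationary random signal whose one-sided power spectral
#' density, in log10 space, is the aperiodic model `B - X * log10(f)` plus
#' optional Gaussian peak bumps: the same additive periodic/aperiodic model
#' the spectral module fits. Defaults mirror the measurement conditions the
#' pipeline targets: 250 Hz sampling and 6 minutes of continuous signal.
#'
#' @param exponent Aperiodic exponent X (dimensionless, > 0 for 1/f-like
#'   signals; 0 gives white noise). Typical cortical values 0.5-3.5.
#' @param offset Aperiodic offset B: log10 power density at 1 Hz.
#' @param peaks List of oscillatory peaks, each `c(center_hz, height,
#'   bandwidth_hz)`: height in log10-power units above the aperiodic
#'   component, bandwidth = 2 standard deviations of the Gaussian bump
#'   (the specparam bandwidth convention).
#' @param fs Sampling rate in Hz.
#' @param duration Signal duration in seconds.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `signal_spec`.
#' @seealso [gen_aperiodic_signal()]
#' @export
signal_spec <- function(exponent, offset = 1, peaks = list(), fs = 250,
                        duration = 360, seed = 1L) {
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent))
  stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset))
  if (fs <= 0) stop("fs must be positive")
  if (duration <= 0) stop("duration must be positive")
  peaks <- normalize_peaks(peaks)
  if (nrow(peaks)) {
    bad <- peaks$center_hz <= 0 | peaks$center_hz >= fs / 2
    if (any(bad)) {
      stop(sprintf(
        "peak center(s) %s Hz outside the open Nyquist range (0, %g) Hz",
        paste(peaks$center_hz[bad], collapse = ", "), fs / 2
      ))
    }
    if (any(peaks$bandwidth_hz <= 0)) stop("peak bandwidth must be positive")
  }
  structure(
    list(
      exponent = exponent, offset = offset, peaks = peaks,
      fs = fs, duration = duration, seed = as.integer(seed)
    ),
    class = "signal_spec"
  )
}

# accept list of length-3 vectors or a data.frame(center_hz, height, bandwidth_hz)
normalize_peaks <- function(peaks) {
  if (is.data.frame(peaks)) {
    stopifnot(all(c("center_hz", "height", "bandwidth_hz") %in% names(peaks)))
    return(peaks[c("center_hz", "height", "bandwidth_hz")])
  }
  if (length(peaks) == 0L) {
    return(data.frame(
      center_hz = numeric(0), height = numeric(0), bandwidth_hz = numeric(0)
    ))
  }
  stopifnot(all(vapply(peaks, length, 1L) == 3L))
  m <- do.call(rbind, peaks)
  data.frame(center_hz = m[, 1], height = m[, 2], bandwidth_hz = m[, 3])
}

# log10 one-sided PSD of the generating model at frequencies f > 0
aperiodic_log_psd <- function(f, offset, exponent, peaks) {
  y <- offset - exponent * log10(f)
  if (nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      sdev <- peaks$bandwidth_hz[i] / 2
      y <- y + peaks$height[i] * exp(-(f - peaks$center_hz[i])^2 / (2 * sdev^2))
    }
  }
  y
}

#' Generate a signal with a prescribed aperiodic spectrum
#'
#' Frequency-domain synthesis: Fourier amplitudes are set deterministically
#' from the target one-sided PSD (`sqrt(PSD)` scaling) and phases are drawn
#' uniformly at random, then the spectrum is inverse-transformed. The sample
#' spectrum of the output therefore follows the prescribed log-linear
#' aperiodic shape (plus any Gaussian peak bumps) up to spectral-estimator
#' noise, and the signal is exactly zero-mean (zero DC component).
#'
#' @param spec A [signal_spec()].
#' @return Numeric vector of length `round(fs * duration)`.
#' @export
#' @examples
#' x <- gen_aperiodic_signal(signal_spec(exponent = 2, duration = 20, seed = 7))
#' ps <- welch_psd(x, fs = 250)
#' fit_aperiodic_fixed(ps)$exponent
gen_aperiodic_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$fs * spec$duration)
  if (n < 8) stop("signal too short: fs * duration must be at least 8 samples")
  n_half <- n %/% 2
  f <- seq_len(n_half) * spec$fs / n
  log_psd <- aperiodic_log_psd(f, spec$offset, spec$exponent, spec$peaks)
  # |X_k|^2 = S(f_k) * fs * n / 2 makes the raw periodogram density equal S
  amp <- sqrt(10^log_psd * spec$fs * n / 2)
  set.seed(spec$seed)
  phase <- runif(n_half) * 2 * pi
  if (n %% 2 == 0) phase[n_half] <- 0 # Nyquist coefficient must be real
  xf <- complex(modulus = amp, argument = phase)
  full <- complex(length.out = n)
  full[2:(n_half + 1)] <- xf
  idx <- if (n %% 2 == 0) seq_len(n_half - 1L) else seq_len(n_half)
  full[n + 1 - idx] <- Conj(xf[idx])
  Re(fft(full, inverse = TRUE)) / n
}

#' ROI time-series container
#'
#' One subject's matrix of region-of-interest signals with its sampling rate.
#'
#' @param subject_id Subject identifier.
#' @param data ROI x sample numeric matrix.
#' @param roi_labels Region labels, one per row of `data`.
#' @param fs Sampling rate in Hz.
#' @return Object of class `roi_ts`.
#' @export
roi_ts <- function(subject_id, data, roi_labels, fs) {
  data <- as.matrix(data)
  if (nrow(data) != length(roi_labels)) {
    stop("row count of data must equal the number of roi_labels")
  }
  if (fs <= 0) stop("fs must be positive")
  if (!all(is.finite(data))) stop("non-finite samples in ROI time series")
  rownames(data) <- roi_labels
  structure(
    list(
      subject_id = subject_id, roi_labels = roi_labels,
      fs = as.numeric(fs), data = data
    ),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf(
    "<roi_ts> subject %s: %d ROIs x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' Covariate coupling specification for synthetic cohorts
#'
#' Defines one subject-level covariate as a linear function of the subject's
#' mean generating exponent over a set of coupled ROIs, plus Gaussian noise,
#' optionally rescaled to a target mean/SD and rounded to a non-negative
#' count. Spearman correlation is used downstream, so only the monotone
#' (linear) coupling matters; the affine rescale does not change it.
#'
#' @param name Covariate name (column in the subject table).
#' @param rois Labels of the coupled ROIs (empty = uncoupled noise covariate).
#' @param slope Linear coupling slope on the mean generating exponent.
#' @param noise_sd SD of the additive Gaussian noise.
#' @param center,scale Optional target mean and SD applied as an affine
#'   rescale of the raw covariate (e.g. 1.88 / 1.03 for an antiseizure
#'   medication count, 39 / 9.75 for an immediate-recall memory score).
#' @param integer Round to a non-negative integer (for medication counts).
#' @return A list of class `covariate_spec`.
#' @export
covariate_spec <- function(name, rois = character(0), slope = 0, noise_sd = 1,
                           center = 0, scale = NULL, integer = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, noise_sd >= 0)
  structure(
    list(
      name = name, rois = rois, slope = slope, noise_sd = noise_sd,
      center = center, scale = scale, integer = integer
    ),
    class = "covariate_spec"
  )
}

default_covariate_specs <- function(roi_labels) {
  temporal <- grep("temporal|entorhinal|parahippocampal", roi_labels,
    value = TRUE
  )
  frontal <- grep("frontal", roi_labels, value = TRUE)
  list(
    covariate_spec("n_asms",
      rois = temporal, slope = 1, noise_sd = 0.08,
      center = 1.88, scale = 1.03, integer = TRUE
    ),
    covariate_spec("memory_score",
      rois = c(temporal, frontal), slope = -1, noise_sd = 0.08,
      center = 39.01, scale = 9.75
    )
  )
}

#' Two-group cohort design for synthetic E/I studies
#'
#' Describes a case/control cohort with per-ROI generating aperiodic
#' parameters: a baseline exponent (and offset) map, an additive case-group
#' exponent shift map, between-subject noise, and covariates monotonically
#' coupled to regional exponents. Default group sizes (67 cases vs 35
#' controls) mirror a typical clinical temporal-lobe-epilepsy sample; default
#' baseline exponents are drawn once (deterministically from `seed`) in the
#' realistic 1.2-1.8 range for 1-35 Hz source-EEG fits.
#'
#' Between-subject variability is modeled as independent per-ROI Gaussian
#' noise (`roi_noise_sd`) plus an optional spatially uniform per-subject
#' offset (`subject_sd`, default 0).
#'
#' @param n_per_group Integer vector of two group sizes (cases, controls).
#' @param groups Two group labels.
#' @param roi_labels Exactly 68 unique ROI labels.
#' @param baseline_exponent_map,baseline_offset_map Per-ROI generating values;
#'   `NULL` draws them deterministically from `seed`.
#' @param group_effect_map,offset_effect_map Per-ROI additive shift applied to
#'   the case group; a scalar is recycled. See [roi_effect_map()].
#' @param covariate_specs List of [covariate_spec()] objects.
#' @param subject_sd SD of the global per-subject exponent offset.
#' @param roi_noise_sd SD of independent per-subject, per-ROI exponent noise.
#' @param offset_noise_sd SD of per-subject, per-ROI offset noise.
#' @param peaks Oscillatory peaks added to every synthesized signal (default:
#'   a 10 Hz alpha peak, height 0.4 log10-power, bandwidth 2 Hz).
#' @param fs,duration Sampling rate (Hz) and duration (s) of synthesized
#'   signals.
#' @param seed Integer master seed; per-subject signal seeds are derived by
#'   counter offset so subsets are reproducible.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(67L, 35L), groups = c("TLE", "HC"),
                          roi_labels = dk_labels(),
                          baseline_exponent_map = NULL,
                          baseline_offset_map = NULL,
                          group_effect_map = 0,
                          offset_effect_map = 0,
                          covariate_specs = default_covariate_specs(roi_labels),
                          subject_sd = 0, roi_noise_sd = 0.2,
                          offset_noise_sd = 0.1,
                          peaks = list(c(10, 0.4, 2)),
                          fs = 250, duration = 360, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group <= 0)) {
    stop("n_per_group must be two positive integers")
  }
  if (any(n_per_group < 2L)) stop("each group needs at least 2 subjects")
  stopifnot(length(groups) == 2L, !anyDuplicated(groups))
  if (length(roi_labels) != 68L || anyDuplicated(roi_labels)) {
    stop("roi_labels must be exactly 68 unique labels")
  }
  nroi <- length(roi_labels)
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(baseline_exponent_map)) {
    baseline_exponent_map <- runif(nroi, 1.2, 1.8)
  }
  if (is.null(baseline_offset_map)) {
    baseline_offset_map <- runif(nroi, 0.8, 1.2)
  }
  align_map <- function(m, what) {
    if (length(m) == 1L) m <- rep(m, nroi)
    if (!is.null(names(m))) {
      if (!all(names(m) %in% roi_labels)) {
        stop(sprintf("%s has names not in roi_labels", what))
      }
      full <- setNames(rep(0, nroi), roi_labels)
      full[names(m)] <- m
      m <- full
    }
    if (length(m) != nroi) stop(sprintf("%s must align to roi_labels", what))
    setNames(as.numeric(m), roi_labels)
  }
  structure(
    list(
      n_per_group = n_per_group, groups = groups, roi_labels = roi_labels,
      baseline_exponent_map = align_map(baseline_exponent_map, "baseline_exponent_map"),
      baseline_offset_map = align_map(baseline_offset_map, "baseline_offset_map"),
      group_effect_map = align_map(group_effect_map, "group_effect_map"),
      offset_effect_map = align_map(offset_effect_map, "offset_effect_map"),
      covariate_specs = covariate_specs,
      subject_sd = subject_sd, roi_noise_sd = roi_noise_sd,
      offset_noise_sd = offset_noise_sd,
      peaks = normalize_peaks(peaks), fs = fs, duration = duration,
      seed = seed
    ),
    class = "cohort_design"
  )
}

#' Build a per-ROI effect map from named ROIs
#'
#' @param rois ROI labels carrying the effect.
#' @param value Additive shift applied in those ROIs.
#' @param roi_labels Full label set (default [dk_labels()]).
#' @return Named numeric vector over `roi_labels` (0 outside `rois`).
#' @export
roi_effect_map <- function(rois, value, roi_labels = dk_labels()) {
  if (!all(rois %in% roi_labels)) stop("unknown ROI label(s) in rois")
  m <- setNames(rep(0, length(roi_labels)), roi_labels)
  m[rois] <- value
  m
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Case subjects' per-ROI generating exponents equal
#' `baseline + group_effect` (controls get baseline only), plus independent
#' per-ROI noise and an optional global subject offset; offsets are generated
#' analogously. Covariates are linear functions of each subject's mean
#' generating exponent over their coupled ROIs plus Gaussian noise. All
#' ground-truth parameters are returned alongside the data in `$truth`.
#'
#' @param design A [cohort_design()].
#' @param signals If `TRUE`, also synthesize per-subject [roi_ts] signal
#'   matrices via [gen_aperiodic_signal()] (68 ROIs x `fs * duration`
#'   samples each; substantially slower). If `FALSE` (default) only the
#'   generating exponent/offset tables are returned, which is the appropriate
#'   scale for calibration and power simulations.
#' @return A list of class `ei_cohort` with elements `subjects` (data.frame:
#'   subject_id, group, covariates), `exponents` and `offsets` (subject x ROI
#'   matrices of generating values), `series` (list of [roi_ts] or `NULL`)
#'   and `truth` (design echo plus latent draws).
#' @export
gen_cohort <- function(design, signals = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  n1 <- design$n_per_group[1]
  n2 <- design$n_per_group[2]
  n <- n1 + n2
  nroi <- length(design$roi_labels)
  subject_id <- sprintf("sub-%03d", seq_len(n))
  group <- rep(design$groups, c(n1, n2))
  is_case <- group == design$groups[1]

  set.seed(design$seed + 1L)
  delta <- rnorm(n, 0, design$subject_sd)
  eps <- matrix(rnorm(n * nroi, 0, design$roi_noise_sd), n, nroi)
  gen_x <- matrix(design$baseline_exponent_map, n, nroi, byrow = TRUE) +
    outer(as.numeric(is_case), design$group_effect_map) + delta + eps
  eps_off <- matrix(rnorm(n * nroi, 0, design$offset_noise_sd), n, nroi)
  gen_b <- matrix(design$baseline_offset_map, n, nroi, byrow = TRUE) +
    outer(as.numeric(is_case), design$offset_effect_map) + eps_off
  dimnames(gen_x) <- dimnames(gen_b) <- list(subject_id, design$roi_labels)

  subjects <- data.frame(
    subject_id = subject_id, group = group, stringsAsFactors = FALSE
  )
  covariate_raw <- list()
  for (cs in design$covariate_specs) {
    base <- if (length(cs$rois)) {
      rowMeans(gen_x[, cs$rois, drop = FALSE])
    } else {
      rep(0, n)
    }
    raw <- cs$slope * base + rnorm(n, 0, cs$noise_sd)
    val <- raw
    if (!is.null(cs$scale)) {
      s <- sd(raw)
      val <- cs$center + if (s > 0) cs$scale * (raw - mean(raw)) / s else 0
    }
    if (isTRUE(cs$integer)) val <- pmax(0, round(val))
    covariate_raw[[cs$name]] <- raw
    subjects[[cs$name]] <- val
  }

  series <- NULL
  if (signals) {
    nsamp <- round(design$fs * design$duration)
    series <- vector("list", n)
    for (s in seq_len(n)) {
      mat <- matrix(0, nroi, nsamp)
      for (r in seq_len(nroi)) {
        sp <- signal_spec(
          exponent = gen_x[s, r], offset = gen_b[s, r],
          peaks = design$peaks, fs = design$fs, duration = design$duration,
          seed = design$seed + 1000L + (s - 1L) * nroi + r
        )
        mat[r, ] <- gen_aperiodic_signal(sp)
      }
      series[[s]] <- roi_ts(subject_id[s], mat, design$roi_labels, design$fs)
    }
    names(series) <- subject_id
  }

  structure(
    list(
      subjects = subjects, exponents = gen_x, offsets = gen_b,
      series = series,
      truth = list(
        design = design, exponents = gen_x, offsets = gen_b,
        subject_offset = delta, covariate_raw = covariate_raw
      )
    ),
    class = "ei_cohort"
  )
}

#' @export
print.ei_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf(
    "<ei_cohort> %s subjects (%s), %d ROIs%s\n",
    nrow(x$subjects),
    paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = " + "),
    ncol(x$exponents),
    if (is.null(x$series)) ", tables only" else ", with signals"
  ))
  invisible(x)
}

#' Multi-donor probe panel design
#'
#' Describes a synthetic probe-level gene-expression panel emulating a
#' multi-donor post-mortem microarray atlas: per-gene latent regional
#' profiles with a planted Spearman correlation against a supplied regional
#' exponent map, probe-level noise around the gene profile, donor-level
#' reproducibility controlled by `cross_donor_consistency`, and
#' above-background detection flags drawn per sample.
#'
#' @param n_donors Number of donor brains (>= 2; default 6, the size of the
#'   standard human atlas).
#' @param regions Region labels (prefixed `lh_`/`rh_`; default all 68
#'   Desikan-Killiany ROIs).
#' @param genes Gene symbols (default the 22-gene panel of
#'   [epilepsy_gene_panel()]).
#' @param probes_per_gene Probes indexing each gene (default 2).
#' @param cross_donor_consistency Target correlation of a probe's regional
#'   profile between any two donors, in \[-1, 1\] (negative values only
#'   meaningful for 2 donors). Scalar or per-probe vector.
#' @param above_background_rate Per-sample probability that a measurement is
#'   flagged above background. Scalar or per-probe vector in \[0, 1\].
#' @param planted_rho Per-gene target Spearman correlation between the gene's
#'   region-mean expression and the supplied exponent map, in \[-1, 1\].
#'   Scalar or per-gene vector (recycled).
#' @param probe_noise_sd SD of probe-specific deviation from the gene latent
#'   profile (latent profiles are unit-variance).
#' @param samples_per_region Tissue samples per region per donor.
#' @param region_coverage Fraction of regions each donor covers (1 = all).
#' @param seed Integer seed.
#' @return Object of class `probe_panel_design`.
#' @export
probe_panel_design <- function(n_donors = 6L, regions = dk_labels(),
                               genes = epilepsy_gene_panel(),
                               probes_per_gene = 2L,
                               cross_donor_consistency = 0.85,
                               above_background_rate = 0.95,
                               planted_rho = 0,
                               probe_noise_sd = 0.2,
                               samples_per_region = 1L,
                               region_coverage = 1,
                               seed = 1L) {
  n_donors <- as.integer(n_donors)
  if (n_donors < 2L) stop("n_donors must be >= 2")
  if (anyDuplicated(genes)) stop("genes must be unique")
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  if (any(planted_rho < -1 | planted_rho > 1)) {
    stop("planted_rho must lie in [-1, 1]")
  }
  if (any(cross_donor_consistency < -1 | cross_donor_consistency > 1)) {
    stop("cross_donor_consistency must lie in [-1, 1]")
  }
  if (any(cross_donor_consistency < 0) && n_donors > 2L) {
    stop("negative cross_donor_consistency requires n_donors = 2")
  }
  if (any(above_background_rate < 0 | above_background_rate > 1)) {
    stop("above_background_rate must lie in [0, 1]")
  }
  if (region_coverage <= 0 || region_coverage > 1) {
    stop("region_coverage must lie in (0, 1]")
  }
  n_probes <- length(genes) * probes_per_gene
  structure(
    list(
      n_donors = n_donors, regions = regions, genes = genes,
      probes_per_gene = as.integer(probes_per_gene),
      cross_donor_consistency = rep_len(cross_donor_consistency, n_probes),
      above_background_rate = rep_len(above_background_rate, n_probes),
      planted_rho = rep_len(planted_rho, length(genes)),
      probe_noise_sd = probe_noise_sd,
      samples_per_region = as.integer(samples_per_region),
      region_coverage = region_coverage,
      seed = as.integer(seed)
    ),
    class = "probe_panel_design"
  )
}

#' Generate a multi-donor probe-level expression panel
#'
#' Gene latent profiles are built on the Gaussian-copula scale: normal scores
#' of the exponent-map ranks are mixed with independent noise at the Pearson
#' correlation `2 * sin(pi * rho / 6)` so that the Spearman correlation with
#' the map approximates the planted `rho`. Probe profiles add probe-specific
#' noise; each donor's profile shares a `sqrt(consistency)` loading on the
#' probe latent so any two donors correlate at approximately
#' `cross_donor_consistency`. Expression intensities are `2^(8 + profile)`
#' (monotone in the latent, so Spearman-based downstream analyses are
#' unaffected by the scale choice).
#'
#' @param design A [probe_panel_design()].
#' @param exponent_map Per-region exponent values, length
#'   `length(design$regions)` (named vectors are checked against the region
#'   labels).
#' @return data.frame with columns donor_id, sample_id, probe_id, gene,
#'   region_id, hemisphere, x_mm, y_mm, z_mm, expression, above_background;
#'   ground truth (latent profiles, design echo) in `attr(, "truth")`.
#' @export
gen_probe_panel <- function(design, exponent_map) {
  stopifnot(inherits(design, "probe_panel_design"))
  nreg <- length(design$regions)
  if (length(exponent_map) != nreg) {
    stop("exponent_map length must equal the number of regions")
  }
  if (!is.null(names(exponent_map))) {
    if (!setequal(names(exponent_map), design$regions)) {
      stop("names of exponent_map do not match design regions")
    }
    exponent_map <- exponent_map[design$regions]
  }
  set.seed(design$seed)
  zmap <- qnorm((rank(exponent_map, ties.method = "average") - 0.5) / nreg)
  zmap <- as.numeric(scale(zmap)) # exact unit variance

  genes <- design$genes
  ppg <- design$probes_per_gene
  centroids <- dk_centroids(design$regions)
  donors <- sprintf("donor-%02d", seq_len(design$n_donors))

  # tissue samples are drawn once per donor and shared across all probes
  donor_samples <- lapply(seq_along(donors), function(di) {
    covered <- if (design$region_coverage < 1) {
      sort(sample(nreg, max(3L, round(design$region_coverage * nreg))))
    } else {
      seq_len(nreg)
    }
    reg <- rep(covered, each = design$samples_per_region)
    rep_i <- rep(seq_len(design$samples_per_region), times = length(covered))
    jit <- matrix(runif(3 * length(reg), -0.5, 0.5), ncol = 3)
    data.frame(
      donor_id = donors[di],
      sample_id = sprintf("%s_%s_s%d", donors[di], design$regions[reg], rep_i),
      region_idx = reg,
      region_id = design$regions[reg],
      hemisphere = centroids$hemisphere[reg],
      x_mm = centroids$x_mm[reg] + jit[, 1],
      y_mm = centroids$y_mm[reg] + jit[, 2],
      z_mm = centroids$z_mm[reg] + jit[, 3],
      stringsAsFactors = FALSE
    )
  })

  gene_latent <- matrix(NA_real_, nreg, length(genes),
    dimnames = list(design$regions, genes)
  )
  rows <- vector("list", length(genes) * ppg * design$n_donors)
  k <- 0L
  probe_latents <- list()
  for (gi in seq_along(genes)) {
    rho <- design$planted_rho[gi]
    r <- 2 * sin(pi * rho / 6)
    lat_g <- r * zmap + sqrt(1 - r^2) * rnorm(nreg)
    gene_latent[, gi] <- lat_g
    for (pj in seq_len(ppg)) {
      pidx <- (gi - 1L) * ppg + pj
      probe_id <- sprintf("%s_p%02d", genes[gi], pj)
      pn <- design$probe_noise_sd
      lat_p <- if (pn > 0) {
        (lat_g + pn * rnorm(nreg)) / sqrt(1 + pn^2)
      } else {
        lat_g
      }
      probe_latents[[probe_id]] <- lat_p
      cc <- design$cross_donor_consistency[pidx]
      abr <- design$above_background_rate[pidx]
      for (di in seq_along(donors)) {
        profile <- if (cc >= 0) {
          sqrt(cc) * lat_p + sqrt(1 - cc) * rnorm(nreg)
        } else if (di == 1L) {
          lat_p
        } else {
          cc * lat_p + sqrt(1 - cc^2) * rnorm(nreg)
        }
        ds <- donor_samples[[di]]
        k <- k + 1L
        rows[[k]] <- data.frame(
          donor_id = ds$donor_id,
          sample_id = ds$sample_id,
          probe_id = probe_id,
          gene = genes[gi],
          region_id = ds$region_id,
          hemisphere = ds$hemisphere,
          x_mm = ds$x_mm, y_mm = ds$y_mm, z_mm = ds$z_mm,
          expression = 2^(8 + profile[ds$region_idx]),
          above_background = as.logical(rbinom(nrow(ds), 1, abr)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  panel <- do.call(rbind, rows[seq_len(k)])
  rownames(panel) <- NULL
  attr(panel, "truth") <- list(
    design = design, zmap = zmap, gene_latent = gene_latent,
    probe_latent = probe_latents, exponent_map = exponent_map
  )
  panel
}
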