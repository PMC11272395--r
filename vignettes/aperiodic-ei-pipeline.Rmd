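---
title: "From ROI time series to E/I conclusions: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ROI time series to E/I conclusions: models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexei)
```

## The measurement model

apexei analyzes resting-state EEG that has already been source-reconstructed
and reduced to the 68 cortical regions of the Desikan–Killiany atlas (mean
time series across each region's vertices). Everything upstream —
acquisition, artifact and interictal-discharge removal, forward and inverse
modelling — is out of scope; the pipeline's contract starts at a
`roi_ts` object: 68 signals at a common sampling rate (250 Hz by
convention), at least several minutes long.

Each ROI signal is turned into a one-sided power spectral density with
Welch's method: periodic Hann window, 5 s segments, 50% overlap, per-segment
mean removal, trailing partial segment discarded. Five-second windows force
a 0.2 Hz frequency resolution at any sampling rate. Two details the
procedure leaves open are resolved conventionally and flagged here:
segments are detrended by mean removal only (no linear detrend), and the
spectrum is scaled as a density (power per Hz), which makes the Parseval
check `sum(psd) * df ≈ var(x)` hold and fixes the absolute meaning of the
offset.

The spectrum between 1 and 35 Hz (endpoints inclusive) is then decomposed
into an aperiodic component and Gaussian oscillatory peaks. In log10 power
the aperiodic model is linear in log10 frequency:

$$A(f) = B - X \log_{10} f,$$

with offset $B$ (log10 power density at 1 Hz, where $\log_{10} 1 = 0$) and
exponent $X$ (dimensionless; the negative log-log slope). Only the *fixed*
mode is implemented — a single 1/f-like characteristic with no spectral
knee — because cortical spectra in this band show no bend in log-log space;
a knee mode is a deliberate non-goal. The logarithm base is 10 throughout,
so offsets and exponents land on the scales published for this estimator
family.

### The fitting loop

`parameterize_spectrum()` follows the specparam algorithm structure:

1. **Robust aperiodic fit** (`fit_aperiodic_fixed()`): ordinary least
   squares of log10 power on log10 frequency; residuals are clipped below
   at zero and points whose clipped residual exceeds the 2.5th percentile
   of that clipped distribution are dropped; the line is refit on the
   retained points. Oscillatory peaks only ever push power *above* the
   aperiodic component, so discarding high-residual points de-biases the
   slope without modelling the peaks. On an exact power law all residuals
   are zero and both passes coincide with OLS (the retention threshold
   carries a 1e-12 tolerance so floating-point noise cannot drop points).
2. **Iterative peak extraction** from the flattened spectrum (log10 power
   minus the aperiodic fit): repeatedly take the maximum; stop when it
   falls below `peak_threshold × sd(flattened)` or below
   `min_peak_height`; guess the bandwidth from the half-height span;
   subtract the guessed Gaussian and repeat. Guesses whose center sits
   within one standard deviation of a fit-range edge are dropped, as is the
   lower of two guesses closer than 0.75 times their summed standard
   deviations.
3. **Joint refinement**: all Gaussians are refit simultaneously by bounded
   L-BFGS-B (centers within ±2 SD of their guess, heights non-negative,
   SDs within half the peak-width limits) with an analytic gradient. If the
   optimizer fails or does not converge, the iterative guesses are kept and
   the result is flagged `refine_converged = FALSE`.
4. **Aperiodic refit** on the peak-removed spectrum (plain OLS), and
   goodness-of-fit: $R^2$ as the squared correlation between the modelled
   and observed log10 spectrum, plus the mean absolute error in log10
   units.

Default hyperparameters (`fit_hyperparams()`): fit range [1, 35] Hz, peak
width limits [0.5, 12] Hz, unbounded peak count, peak threshold 2, minimum
peak height 0, fixed aperiodic mode. Three numerical choices deserve
explicit mention:

* **Bandwidth convention.** A peak's bandwidth is *twice its Gaussian
  standard deviation* (the specparam reporting convention), both in
  `signal_spec()` peaks and in fitted `peaks` tables, so planted and
  recovered bandwidths are directly comparable.
* **Unbounded peaks still terminate.** The threshold rule guarantees
  termination; a safety cap of `floor(n_points / 3)` peaks exists purely
  against pathological inputs and raises a warning when hit.
* **A 1e-9 absolute height floor** in the stopping rule prevents
  machine-epsilon ripples on noiseless spectra from being reported as
  peaks. With `min_peak_height = 0` and genuinely noisy spectra, small
  estimator-noise peaks (heights of a few hundredths) *are* reported —
  that is the faithful behavior of these hyperparameters, and exponent
  recovery is unaffected.

The exponent and offset are carried through the entire inferential
machinery symmetrically: every group contrast and correlation can be run on
either measure (`measure = "exponent"` or `"offset"`).

## Inference

**Group contrasts** use a mass-univariate permutation test
(`mass_permutation_test()`): a pooled-variance Student t per ROI (the
classical default in this literature; an unpooled switch exists but is off
by default), with a null built from label permutations applied to all ROIs
jointly — one shared permutation stream preserves the spatial dependence of
the null and makes a test on a column subset reproduce the full run
exactly. The two-tailed empirical p uses the `+1/(m+1)` correction, so p is
a valid permutation p-value and never zero; 5000 permutations by default.
Units with all-equal values are flagged degenerate and get t = 0, p = 1.
BH-FDR is applied across the 68 ROIs (or across genes), with α = 0.05.

**Covariate correlations** (`roi_covariate_correlation()`) are Spearman
correlations of each ROI's measure with a clinical covariate across
subjects, pairwise-deleted for missingness with per-ROI n reported, BH-FDR
across ROIs. The Spearman p uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; ties get average ranks.

**Gene-map correlations** (`gene_map_correlation()`) correlate each gene's
regional expression with a regional exponent map across the 68 regions,
BH-FDR across the gene panel (22 genes by default). Which map to use is a
genuinely open choice; this package adopts the *case-group mean exponent
per ROI* (the most direct "regional E/I load" summary) and exposes the map
as an explicit argument, so a t-map or any other aggregation can be
substituted.

**Regression** (`ols_f_tests()`) reports marginal (Type III-style) partial
F tests per term — each term's columns are dropped from the full design,
including main effects in the presence of their interaction — which is what
the two standard models here need (exponent ~ ASMs + memory + ASMs×memory;
memory ~ exponent + ASMs + exponent×ASMs). Covariates enter uncentered by
default; centering is the caller's choice since the marginal F of the
interaction is unaffected.

## The synthetic world

The generators are validation scaffolding: the source data this pipeline
targets carry no public generative model, so every distributional choice
below is this package's own, made once and documented, not a claim about
real patients.

**Signals** (`gen_aperiodic_signal()`) are synthesized in the frequency
domain: Fourier amplitudes set deterministically to $\sqrt{S(f)}$ for the
target PSD (the aperiodic model plus Gaussian log-power bumps), phases
drawn uniformly, inverse transform. Deterministic amplitudes mean the
sample spectrum follows the target up to windowing leakage only, which is
exactly what a fitting-stage validation wants; real EEG additionally has
amplitude fluctuations, non-stationarity and artifacts that this generator
deliberately does not emulate. A green recovery test therefore establishes
estimator correctness, not robustness to physiological nuisance.

**Cohorts** (`gen_cohort()`). Generating exponents are
`baseline + effect·[case] + noise`. Defaults: baselines drawn once per
design from U(1.2, 1.8) — the realistic range for 1–35 Hz source-EEG fits —
offsets from U(0.8, 1.2); between-subject noise is independent per-ROI
Gaussian with SD 0.2, the dominant scale of between-subject exponent
spread; an optional spatially uniform per-subject offset (`subject_sd`)
exists for scenarios that need globally coupled maps and defaults to 0,
keeping ROI units approximately independent under the null (the regime the
pooled calibration diagnostics assume). Group sizes default to 67 cases vs
35 controls, mirroring a typical clinical sample. Covariates are linear in
the subject's mean generating exponent over their coupled ROIs plus
Gaussian noise — Spearman is used downstream, so only monotonicity matters —
optionally rescaled to clinical units (medication counts: mean 1.88, SD
1.03, rounded non-negative; memory scores: mean 39.0, SD 9.75). Signal
synthesis (`signals = TRUE`) adds a 10 Hz alpha peak (height 0.4, bandwidth
2 Hz) by default. Calibration and power simulations run at the exponent
*table* level: synthesizing and refitting thousands of six-minute signals
adds only the ~0.01–0.02 estimator noise documented above at two orders of
magnitude more compute, so table-level nulls are the appropriate scale.

**Probe panels** (`gen_probe_panel()`). Gene latent profiles live on a
Gaussian-copula scale: normal scores of the exponent-map ranks mixed with
noise at Pearson $r = 2\sin(\pi\rho/6)$, so the Spearman correlation with
the map approximates the planted $\rho$. Probe profiles add probe noise
(SD 0.2); donors load on the probe latent with $\sqrt{c}$ so any two donors
correlate at approximately the designed consistency $c$ (default 0.85,
giving differential stabilities around 0.8 — the upper, curated-panel end
of real atlas distributions; $c = 1$ reproduces profiles exactly and yields
stability 1). Six donors by default, matching the standard human atlas.
Expression is $2^{8 + \text{latent}}$ — an arbitrary monotone intensity
scale, irrelevant to all rank-based downstream steps. Above-background
flags are Bernoulli per sample. Donor-averaging and the double
normalization attenuate a planted $\rho = 0.45$ by only a few percent at
these defaults. Region centroids (`dk_centroids()`) are a synthetic
hemisphere-signed grid (20 mm spacing, samples jittered within 1 mm), built
to exercise the 2 mm/hemisphere assignment logic — they are not anatomical
coordinates. The default 22-gene panel is likewise a synthetic stand-in of
real epilepsy/E–I gene symbols.

## Transcriptomics numerical choices

* **Intensity filter**: a probe is discarded when below background in
  ≥ 50% of samples — the boundary case (exactly half) is discarded.
* **Differential stability**: mean pairwise Spearman of donor regional
  profiles over the common regions of each pair; pairs sharing fewer than
  3 regions, or containing a constant profile, are excluded with a
  warning; fewer than 2 donors is an error.
* **Probe selection ties** are broken by lexicographically smallest probe
  id — deterministic across platforms and input orders.
* **Robust sigmoid**: $x_{norm} = 1/(1+\exp(-(x - \langle x\rangle)/IQR_x))$
  with $\langle x\rangle$ the median. The *normalized* interquartile range
  is not defined by its printed sources; this package adopts
  $(Q_{75}-Q_{25})/1.349$, the SD-consistent scaling under normality, and
  offers the plain IQR behind `iqr_scale = "raw"` rather than guessing
  intent. Quartiles are type-7 (linear interpolation). Zero IQR returns
  all 0.5 with a warning. After the sigmoid, values are rescaled to attain
  0 and 1 exactly.
* **Order of operations**: per donor, each tissue sample is normalized
  across genes, samples are averaged within region, then each gene is
  normalized across the donor's regions; donor matrices are averaged
  elementwise over the donors covering each region. Regions no donor
  covers are `NA` rows, logged — never silently dropped.

## Determinism and orchestration

Every generator takes an explicit integer seed; per-subject and per-probe
substreams are derived by counter offsets so subsets reproduce exactly.
The permutation stream is seeded independently of the data. `run_config()`
carries a mandatory seed, and the MD5 hash of the whole configuration is
recorded in every run report, so a rerun with one changed parameter is
detectable and a rerun with the same config and seed writes byte-identical
tables. Configs serialize to JSON; ROI series and all result tables are
TSV (this build's environment provides no HDF5 binding, so the delimited
interchange format is the only on-disk representation of time series).

## Known limitations

* No knee-mode aperiodic fit: spectra with a genuine bend in 1–35 Hz will
  bias the exponent, and the high $R^2$/low MAE QC fields are the only
  guard.
* The signal generator's stationary, deterministic-amplitude spectra make
  recovery tests sharper than real EEG would allow; robustness to
  artifacts, non-stationarity and spatial leakage is untested by design.
* With the published hyperparameters (unbounded peaks, zero minimum
  height), estimator noise yields small spurious peaks on real-length
  recordings; consumers of the peak table should filter on height.
* The gene stage models neither probe re-annotation (a valid gene symbol
  per probe is an input-schema requirement) nor the background-noise
  physics of microarrays (above-background flags are taken as given).
* Negative cross-donor consistency is only exactly representable for two
  donors; for more donors it is rejected rather than approximated.
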