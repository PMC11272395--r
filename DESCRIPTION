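Package: apexei
Title: Aperiodic EEG Exponent Pipelines for Excitation/Inhibition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to carry resting-state EEG region-of-interest time series
    through to excitation/inhibition (E/I) conclusions: Welch power spectral
    density estimation, specparam-style parameterization of the spectrum into
    aperiodic (offset, exponent) and periodic (Gaussian peak) components over
    1-35 Hz, mass-univariate permutation t-tests with Benjamini-Hochberg FDR
    control, node-wise Spearman correlation with clinical covariates,
    reduction of multi-donor probe-level cortical gene-expression panels
    (intensity filtering, differential stability, sample-to-region assignment,
    robust sigmoid normalization, donor averaging), and correlation of the
    resulting gene maps with regional exponent maps. A synthetic-data module
    generates every pipeline input with known ground truth: colored-noise
    signals with prescribed aperiodic parameters and oscillatory peaks,
    two-group cohorts with planted regional effects and covariate couplings,
    and multi-donor probe panels with planted gene-map correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
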