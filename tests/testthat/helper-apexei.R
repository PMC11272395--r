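# shared fixtures, all generated in code

# tiny hand-buildable probe panel: one row per (donor, probe, region)
make_panel <- function(donors, probes, regions, expr_fun,
                       above_background = TRUE, gene_of = NULL) {
  grid <- expand.grid(
    donor_id = donors, probe_id = probes, region_id = regions,
    stringsAsFactors = FALSE
  )
  if (is.null(gene_of)) gene_of <- setNames(sub("_p[0-9]+$", "", probes), probes)
  grid$gene <- gene_of[grid$probe_id]
  grid$sample_id <- paste(grid$donor_id, grid$region_id, sep = "_")
  grid$expression <- mapply(expr_fun, grid$donor_id, grid$probe_id, grid$region_id)
  grid$above_background <- above_background
  grid
}

# small multi-ROI synthetic subject built directly from signal specs
make_subject <- function(id, exponents, offsets = NULL, fs = 250,
                         duration = 60, seed = 1, peaks = list()) {
  nroi <- length(exponents)
  if (is.null(offsets)) offsets <- rep(1, nroi)
  labels <- paste0("roi_", seq_len(nroi))
  mat <- t(vapply(seq_len(nroi), function(r) {
    gen_aperiodic_signal(signal_spec(
      exponent = exponents[r], offset = offsets[r], peaks = peaks,
      fs = fs, duration = duration, seed = seed * 100 + r
    ))
  }, numeric(round(fs * duration))))
  roi_ts(id, mat, labels, fs)
}

# independent exhaustive BH step-up oracle (textbook definition)
bh_oracle <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  ord <- order(p)
  sorted <- p[ord]
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}
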