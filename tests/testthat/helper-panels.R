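# Shared fixtures, built in code.

# A deterministic zero-noise single-sample experiment and its fitted basis.
quiet_panel <- function(kind = "tandem", E = 0.31, f = 1, noise = 0,
                        n_replicates = 1, seed = 42, cv = 0, ...) {
  cfg <- synthetic_panel_config(true_efficiency = E, complex_fraction = f,
                                noise_sigma = noise,
                                n_replicates = n_replicates,
                                replicate_cv = cv, seed = seed, ...)
  simulate_pair_spectra(cfg, kind)
}

# Reference basis fitted from a zero-noise panel (exact shapes).
exact_basis <- function(seed = 42) {
  fret_analysis(quiet_panel(seed = seed))$basis
}

# Spectrum carrying an exact linear combination of basis columns for the
# given channel.
mixture_spectrum <- function(basis, channel, amplitudes,
                             sample_id = "mix", replicate = 1) {
  B <- fretunmix:::basis_matrix(basis, channel)
  grid <- basis$grid[[as.character(channel)]]
  emission_spectrum(grid, as.numeric(B %*% amplitudes), sample_id,
                    channel, replicate, "fret_sample")
}

# Unconstrained least-squares oracle (QR), independent of nnls_solve.
ols_coef <- function(A, b) qr.coef(qr(A), b)

# Per-experiment EfA values, one fresh experiment (own references) per seed.
pooled_efa <- function(kind, E, f, seeds, noise = 0.01, cv = 0.10) {
  vapply(seeds, function(s) {
    p <- quiet_panel(kind, E = E, f = f, noise = noise, seed = s, cv = cv)
    suppressWarnings(fret_analysis(p)$results$efa)
  }, numeric(1))
}
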