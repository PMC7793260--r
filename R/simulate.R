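#' Fluorophore photophysical model for the spectrum generator
#'
#' A skew-normal emission band plus per-channel relative excitation
#' efficiencies. The defaults of [default_donor_model()] /
#' [default_acceptor_model()] emulate mKO (emission peak near 559 nm, excited
#' strongly in the 541 nm band and not at 587 nm) and mCherry (peak near
#' 610 nm, excited at both 541 and 587 nm — the 541 nm cross-excitation is
#' the direct-acceptor component the analysis must subtract).
#'
#' @param name Label.
#' @param emission_peak_nm Emission peak in nm.
#' @param emission_width_nm Band width (scale of the skew-normal) in nm, > 0.
#' @param emission_skew Skewness parameter (0 = symmetric; positive = red
#'   tail, as fluorescent-protein emission bands have).
#' @param relative_excitation Named numeric vector: excitation efficiency
#'   (dimensionless, >= 0) per excitation wavelength, names in nm.
#' @param quantum_scale Brightness scale (arbitrary units).
#' @return An object of class `"fluorophore_model"`.
#' @export
fluorophore_model <- function(name, emission_peak_nm, emission_width_nm,
                              emission_skew = 0, relative_excitation,
                              quantum_scale = 1) {
  if (!is.finite(emission_width_nm) || emission_width_nm <= 0) {
    stop("domain error: emission width must be > 0", call. = FALSE)
  }
  if (any(relative_excitation < 0)) {
    stop("domain error: excitation efficiencies must be >= 0", call. = FALSE)
  }
  structure(list(name = name, emission_peak_nm = emission_peak_nm,
                 emission_width_nm = emission_width_nm,
                 emission_skew = emission_skew,
                 relative_excitation = relative_excitation,
                 quantum_scale = quantum_scale),
            class = "fluorophore_model")
}

#' @rdname fluorophore_model
#' @export
default_donor_model <- function() {
  fluorophore_model("mKO-like donor", emission_peak_nm = 559,
                    emission_width_nm = 18, emission_skew = 3,
                    relative_excitation = c("541" = 1.0, "587" = 0.0))
}

#' @rdname fluorophore_model
#' @export
default_acceptor_model <- function() {
  fluorophore_model("mCherry-like acceptor", emission_peak_nm = 610,
                    emission_width_nm = 22, emission_skew = 2,
                    relative_excitation = c("541" = 0.25, "587" = 1.0))
}

excitation_of <- function(m, channel_nm) {
  v <- m$relative_excitation[[as.character(channel_nm)]]
  if (is.null(v)) 0 else v
}

#' Unit-normalized emission shape of a fluorophore on a wavelength grid
#'
#' Skew-normal density \eqn{\phi(z)\Phi(\alpha z)}, \eqn{z =
#' (\lambda - peak)/width}, clipped at zero and scaled to unit Euclidean
#' norm. A truncation note (message) is emitted when the grid does not cover
#' peak +/- 3 widths.
#'
#' @param m A [fluorophore_model()].
#' @param grid Numeric wavelength vector (nm).
#' @return Numeric vector, nonnegative, Euclidean norm 1.
#' @export
emission_shape <- function(m, grid) {
  stopifnot(inherits(m, "fluorophore_model"))
  if (min(grid) > m$emission_peak_nm - 3 * m$emission_width_nm ||
      max(grid) < m$emission_peak_nm + 3 * m$emission_width_nm) {
    message("note: grid truncates the ", m$name, " emission band (does not ",
            "cover peak +/- 3 widths)")
  }
  z <- (grid - m$emission_peak_nm) / m$emission_width_nm
  y <- stats::dnorm(z) * stats::pnorm(m$emission_skew * z)
  y / sqrt(sum(y^2))
}

#' Configuration of the synthetic two-channel FRET spectrum generator
#'
#' Defaults reflect typical in-vivo spectrofluorimeter FRET panels of
#' mKO/mCherry fusions in fixed E. coli suspensions: a 1 nm grid over
#' 550–700 nm (donor excitation, 550 nm long-pass) and 600–700 nm (acceptor
#' excitation, 600 nm long-pass), cellular autofluorescence a few-fold below
#' the fluorophore peaks, additive Gaussian noise of 1% of the peak signal,
#' and ~10% log-normal replicate-to-replicate scatter of expression levels.
#'
#' @param donor,acceptor [fluorophore_model()]s.
#' @param grid_donor_exc,grid_acceptor_exc `c(start, stop, step)` nm grids of
#'   the two emission windows.
#' @param donor_excitation_nm,acceptor_excitation_nm Excitation wavelengths.
#' @param donor_abundance,acceptor_abundance Mean fluorophore abundances
#'   (arbitrary units).
#' @param complex_fraction Fraction f of acceptors bound in donor complexes,
#'   in \[0, 1\].
#' @param true_efficiency Ground-truth transfer efficiency E in \[0, 1).
#' @param kappa Extinction-ratio correction shared with
#'   [fret_calibration()]; the generator scales sensitized emission by
#'   1/kappa so the analyzer's EfA equals 100 f E at zero noise for any
#'   kappa.
#' @param background_scale Autofluorescence amplitude (arbitrary units).
#' @param buffer_level Constant buffer baseline.
#' @param noise_sigma Additive Gaussian noise SD as a fraction of each scan's
#'   peak signal.
#' @param replicate_cv Log-normal coefficient of variation of abundances
#'   across biological replicates.
#' @param n_replicates Number of biological replicates per sample.
#' @param seed Integer RNG seed, recorded in the output manifest.
#' @return An object of class `"synthetic_panel_config"`.
#' @export
synthetic_panel_config <- function(donor = default_donor_model(),
                                   acceptor = default_acceptor_model(),
                                   grid_donor_exc = c(550, 700, 1),
                                   grid_acceptor_exc = c(600, 700, 1),
                                   donor_excitation_nm = 541,
                                   acceptor_excitation_nm = 587,
                                   donor_abundance = 1000,
                                   acceptor_abundance = 1000,
                                   complex_fraction = 1,
                                   true_efficiency = 0.3,
                                   kappa = 1,
                                   background_scale = 200,
                                   buffer_level = 20,
                                   noise_sigma = 0.01,
                                   replicate_cv = 0.10,
                                   n_replicates = 3L,
                                   seed = 1L) {
  if (complex_fraction < 0 || complex_fraction > 1) {
    stop("config error: complex_fraction must be in [0, 1]", call. = FALSE)
  }
  if (true_efficiency < 0 || true_efficiency >= 1) {
    stop("config error: true_efficiency must be in [0, 1)", call. = FALSE)
  }
  if (noise_sigma < 0) {
    stop("config error: noise_sigma must be >= 0", call. = FALSE)
  }
  if (donor_abundance <= 0 || acceptor_abundance <= 0) {
    stop("config error: abundances must be > 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_panel_config")
}

grid_points <- function(g) {
  if (length(g) == 3L && g[[3]] < g[[2]] - g[[1]]) seq(g[[1]], g[[2]], g[[3]])
  else as.numeric(g)
}

# Deterministic broad autofluorescence shape (unit norm per grid).
background_shape_on <- function(grid) {
  y <- exp(-((grid - 580)^2) / (2 * 60^2))
  y / sqrt(sum(y^2))
}

add_noise <- function(intensities, noise_sigma) {
  if (noise_sigma <= 0) return(intensities)
  s <- noise_sigma * max(intensities)
  intensities + stats::rnorm(length(intensities), 0, s)
}

make_scan <- function(cfg, channel_nm, intensities, sample_id, role,
                      replicate = 1L) {
  grid <- grid_points(if (channel_nm == cfg$donor_excitation_nm)
    cfg$grid_donor_exc else cfg$grid_acceptor_exc)
  emission_spectrum(grid, add_noise(intensities, cfg$noise_sigma),
                    sample_id, channel_nm, replicate, role)
}

# Noise-free channel signal for abundances D (donor) and A (acceptor),
# complexed pairs = f * min(D, A), transfer efficiency E.
channel_signal <- function(cfg, channel_nm, D = 0, A = 0, f = 0, E = 0) {
  grid <- grid_points(if (channel_nm == cfg$donor_excitation_nm)
    cfg$grid_donor_exc else cfg$grid_acceptor_exc)
  bg <- cfg$buffer_level + cfg$background_scale * background_shape_on(grid)
  sig <- bg
  exD <- excitation_of(cfg$donor, channel_nm)
  exA <- excitation_of(cfg$acceptor, channel_nm)
  pairs <- f * min(D, A)
  if (D > 0 && exD > 0) {
    # complexed donors lose a fraction E of their excitations to transfer
    quench <- if (D > 0) 1 - E * pairs / D else 1
    sh <- suppressMessages(emission_shape(cfg$donor, grid))
    sig <- sig + sh * (exD * D * cfg$donor$quantum_scale * quench)
  }
  if (A > 0 || pairs > 0) {
    sh <- suppressMessages(emission_shape(cfg$acceptor, grid))
    direct <- exA * A * cfg$acceptor$quantum_scale
    sens <- if (channel_nm == cfg$donor_excitation_nm) {
      # scaled so that EfA = 100 * kappa * sens/direct recovers 100 f E
      excitation_of(cfg$acceptor, cfg$donor_excitation_nm) *
        cfg$acceptor$quantum_scale * E * pairs / cfg$kappa
    } else 0
    sig <- sig + sh * (direct + sens)
  }
  sig
}

simulate_references <- function(cfg) {
  chans <- c(cfg$donor_excitation_nm, cfg$acceptor_excitation_nm)
  out <- list()
  for (ch in chans) {
    grid <- grid_points(if (ch == cfg$donor_excitation_nm)
      cfg$grid_donor_exc else cfg$grid_acceptor_exc)
    out[[paste0("buffer_", ch)]] <-
      make_scan(cfg, ch, rep(cfg$buffer_level, length(grid)),
                "buffer", "buffer")
    out[[paste0("empty_", ch)]] <-
      make_scan(cfg, ch, channel_signal(cfg, ch), "empty_cell", "empty_cell")
    out[[paste0("acceptor_ref_", ch)]] <-
      make_scan(cfg, ch,
                channel_signal(cfg, ch, A = cfg$acceptor_abundance),
                "acceptor_ref", "acceptor_ref")
  }
  out[["donor_ref"]] <-
    make_scan(cfg, cfg$donor_excitation_nm,
              channel_signal(cfg, cfg$donor_excitation_nm,
                             D = cfg$donor_abundance),
              "donor_ref", "donor_ref")
  out
}

sample_kind_params <- function(cfg, kind) {
  switch(kind,
    tandem = list(f = 1, E = cfg$true_efficiency, tied = TRUE),
    negative = list(f = 0, E = cfg$true_efficiency, tied = FALSE),
    pair = ,
    fret_sample = list(f = cfg$complex_fraction, E = cfg$true_efficiency,
                       tied = FALSE),
    stop("config error: unknown sample kind '", kind, "'", call. = FALSE))
}

kind_role <- function(kind) {
  switch(kind, tandem = "tandem", negative = "negative", "fret_sample")
}

simulate_sample_scans <- function(cfg, kind, sample_id) {
  p <- sample_kind_params(cfg, kind)
  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  scans <- list()
  truth <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    ln <- stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (p$tied) ln[2] <- ln[1]  # a tandem fusion has D = A by construction
    D <- cfg$donor_abundance * ln[[1]]
    A <- cfg$acceptor_abundance * ln[[2]]
    for (ch in c(cfg$donor_excitation_nm, cfg$acceptor_excitation_nm)) {
      scans[[length(scans) + 1L]] <-
        make_scan(cfg, ch, channel_signal(cfg, ch, D, A, p$f, p$E),
                  sample_id, kind_role(kind), replicate = r)
    }
    truth[[r]] <- data.frame(
      sample_id = sample_id, replicate = r, kind = kind,
      complex_fraction = p$f, true_efficiency = p$E,
      donor_abundance = D, acceptor_abundance = A,
      expected_efa = 100 * p$f * p$E * min(D, A) / A,
      seed = cfg$seed, stringsAsFactors = FALSE)
  }
  list(scans = scans, ground_truth = do.call(rbind, truth))
}

#' Simulate a complete single-sample FRET experiment
#'
#' Generates, deterministically under `cfg$seed`, all scans an experiment
#' needs: PBS buffer and empty-cell scans in both channels, a donor-only and
#' an acceptor-only reference, and `cfg$n_replicates` sample replicates
#' measured under both donor and acceptor excitation, plus the ground-truth
#' table the generator drew from.
#'
#' @param cfg A [synthetic_panel_config()].
#' @param kind `"tandem"` (f = 1, donor and acceptor abundances tied, the
#'   positive-control analogue), `"negative"` (f = 0, non-interacting pair)
#'   or `"pair"`/`"fret_sample"` (uses `cfg$complex_fraction`).
#' @param sample_id Sample label; defaults to `kind`.
#' @return A list of class `"synthetic_panel"` with `spectra` (list of
#'   [emission_spectrum()]), `ground_truth` (data frame) and `config`.
#' @export
simulate_pair_spectra <- function(cfg, kind = "pair", sample_id = kind) {
  stopifnot(inherits(cfg, "synthetic_panel_config"))
  set.seed(cfg$seed)
  refs <- simulate_references(cfg)
  smp <- simulate_sample_scans(cfg, kind, sample_id)
  structure(list(spectra = c(unname(refs), smp$scans),
                 ground_truth = smp$ground_truth, config = cfg),
            class = "synthetic_panel")
}

#' Simulate a multi-sample FRET panel
#'
#' One shared set of reference scans plus several sample groups, emulating a
#' typical experiment (positive tandem control, negative non-interacting
#' control, FRET pairs under study).
#'
#' @param design List of entries, each a list with `kind`, optional
#'   `sample_id` and optional config overrides (`complex_fraction`,
#'   `true_efficiency`, `donor_abundance`, `acceptor_abundance`,
#'   `n_replicates`).
#' @param cfg Base [synthetic_panel_config()].
#' @return A `"synthetic_panel"` (see [simulate_pair_spectra()]).
#' @export
simulate_panel <- function(design, cfg = synthetic_panel_config()) {
  stopifnot(inherits(cfg, "synthetic_panel_config"))
  if (!length(design)) {
    stop("config error: empty panel design", call. = FALSE)
  }
  ids <- vapply(seq_along(design), function(i) {
    d <- design[[i]]
    if (!is.null(d$sample_id)) d$sample_id else d$kind
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("config error: duplicate sample ids in design (",
         paste(ids[duplicated(ids)], collapse = ", "), ")", call. = FALSE)
  }
  set.seed(cfg$seed)
  refs <- simulate_references(cfg)
  spectra <- unname(refs)
  truth <- list()
  for (i in seq_along(design)) {
    d <- design[[i]]
    cfg_i <- cfg
    for (k in intersect(names(d), c("complex_fraction", "true_efficiency",
                                    "donor_abundance", "acceptor_abundance",
                                    "n_replicates"))) {
      cfg_i[[k]] <- d[[k]]
    }
    smp <- simulate_sample_scans(cfg_i, d$kind, ids[[i]])
    spectra <- c(spectra, smp$scans)
    truth[[i]] <- smp$ground_truth
  }
  structure(list(spectra = spectra, ground_truth = do.call(rbind, truth),
                 config = cfg),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d scans, %d sample replicates, seed %d\n",
              length(x$spectra), nrow(x$ground_truth), x$config$seed))
  invisible(x)
}

#' Write a synthetic panel to disk in the package's exchange formats
#'
#' Writes one spectrum file per scan, a loadable experiment manifest
#' (`manifest.csv`) and the ground-truth table (`ground_truth.tsv`).
#'
#' @param panel A `"synthetic_panel"`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(panel$spectra), function(i) {
    s <- panel$spectra[[i]]
    fn <- sprintf("%03d_%s_exc%g_rep%d.csv", i, gsub("[^A-Za-z0-9_-]", "_",
                                                     s$sample_id),
                  s$excitation_nm, s$replicate)
    write_spectrum(s, file.path(dir, fn))
    data.frame(path = fn, sample_id = s$sample_id, role = s$role,
               excitation_nm = s$excitation_nm, replicate = s$replicate,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(m, manifest_path)
  utils::write.table(panel$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Simulate a muropeptide peak table with known composition metrics
#'
#' Inverts the derived-metric formulas: the generated table has dimer and
#' trimer totals chosen so [degree_of_crosslinkage()] returns
#' `target_crosslinkage` exactly, and a chain-end percentage of
#' `100 / target_chain_length` so [mean_chain_length()] returns
#' `target_chain_length` exactly (at zero noise). Class totals are
#' distributed over plausible species rows in wild-type-like proportions.
#'
#' @param target_chain_length Mean glycan chain length in disaccharide units,
#'   >= 2.
#' @param target_crosslinkage Degree of cross-linkage in percent, in
#'   \[0, 60).
#' @param noise Multiplicative log-normal noise SD applied per species row
#'   (0 = exact).
#' @param seed Integer seed.
#' @param sample_name Name of the single sample column.
#' @return A `"muro_table"`.
#' @export
simulate_muro_table <- function(target_chain_length, target_crosslinkage,
                                noise = 0, seed = 1L,
                                sample_name = "synthetic") {
  if (target_chain_length < 2) {
    stop("config error: chain length must be >= 2 DS", call. = FALSE)
  }
  if (target_crosslinkage < 0 || target_crosslinkage >= 60) {
    stop("config error: cross-linkage must be in [0, 60)", call. = FALSE)
  }
  # trimers fixed at 10% of dimers; solve d/2 + 2(0.1 d)/3 = X
  d <- target_crosslinkage / (0.5 + 0.2 / 3)
  tri <- 0.1 * d
  mono <- 100 - d - tri
  if (mono < 0) {
    stop("config error: infeasible composition (class totals exceed 100%)",
         call. = FALSE)
  }
  ce <- 100 / target_chain_length

  row <- function(species, class, type, lens, mod, in_total, value) {
    data.frame(species = species, oligomer_class = class, row_type = type,
               peptide_lengths = lens, modification = mod,
               in_total = in_total, value = value, stringsAsFactors = FALSE)
  }
  t <- rbind(
    row("dipeptides", "monomer", "species", "2", "-", TRUE, 0.03 * mono),
    row("tripeptides", "monomer", "species", "3", "-", TRUE, 0.09 * mono),
    row("tetrapeptides", "monomer", "species", "4", "-", TRUE, 0.79 * mono),
    row("anhydro", "monomer", "species", NA, "anhydro", TRUE, 0.02 * mono),
    row("LysArg", "monomer", "species", NA, "LysArg", TRUE, 0.07 * mono),
    row("tetratripeptide", "dimer", "species", "4+3", "-", TRUE, 0.08 * d),
    row("tetratetrapeptide", "dimer", "species", "4+4", "-", TRUE, 0.92 * d),
    row("anhydro", "dimer", "species", NA, "anhydro", FALSE, 0.05 * d),
    row("tetratetratetrapeptide", "trimer", "species", "4+4+4", "-", TRUE,
        tri),
    row("Chain ends (anhydro)", "chain_ends", "chain_ends", NA, "anhydro",
        FALSE, ce)
  )
  if (noise > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise^2))
    t$value <- t$value *
      stats::rlnorm(nrow(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  names(t)[names(t) == "value"] <- sample_name
  as_muro_table(t)
}
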