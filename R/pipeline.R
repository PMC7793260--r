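#' Run the full spectral FRET analysis over an experiment
#'
#' End-to-end pipeline: load (or accept in-memory) scans, resample each
#' excitation channel to a common 1 nm grid, subtract the PBS buffer, build
#' the reference basis from the empty-cell, donor-only and acceptor-only
#' scans, unmix every sample replicate in both channels, compute per-replicate
#' acceptor FRET efficiencies and summarize them per sample group.
#'
#' @param x A manifest file path, a `"fret_manifest"` data frame, or a
#'   `"synthetic_panel"` from [simulate_panel()].
#' @param cal A [fret_calibration()].
#' @return An object of class `"fret_experiment"` with elements `basis`,
#'   `unmix_fits`, `results` (per-replicate data frame), `summary`
#'   (per-group data frame) and `fret_results` (list of
#'   [compute_efa()] objects).
#' @export
fret_analysis <- function(x, cal = fret_calibration()) {
  spectra <- if (inherits(x, "synthetic_panel")) {
    x$spectra
  } else {
    m <- if (inherits(x, "fret_manifest")) x else load_manifest(x)
    lapply(seq_len(nrow(m)), function(i) {
      read_spectrum(m$path[[i]], m[i, c("sample_id", "role", "excitation_nm",
                                        "replicate")])
    })
  }
  roles <- vapply(spectra, `[[`, character(1), "role")
  chans <- vapply(spectra, `[[`, numeric(1), "excitation_nm")
  channels <- sort(unique(chans))
  if (length(channels) != 2L) {
    stop("manifest error: expected exactly two excitation channels, found ",
         length(channels), call. = FALSE)
  }

  # common 1 nm grid per channel: the intersection of measured ranges
  grids <- lapply(channels, function(ch) {
    wls <- lapply(spectra[chans == ch], `[[`, "wavelengths")
    lo <- ceiling(max(vapply(wls, min, numeric(1))))
    hi <- floor(min(vapply(wls, max, numeric(1))))
    seq(lo, hi, by = 1)
  })
  names(grids) <- as.character(channels)
  spectra <- lapply(spectra, function(s) {
    resample_to_grid(s, grids[[as.character(s$excitation_nm)]])
  })

  pick <- function(role, ch) {
    i <- which(roles == role & chans == ch)
    if (!length(i)) {
      stop("manifest error: missing ", role, " at excitation ", ch, " nm",
           call. = FALSE)
    }
    spectra[[i[[1]]]]
  }
  donor_ch <- chans[match("donor_ref", roles)]
  if (is.na(donor_ch)) {
    stop("manifest error: missing donor_ref scan", call. = FALSE)
  }
  acceptor_ch <- setdiff(channels, donor_ch)
  buffers <- stats::setNames(lapply(channels, pick, role = "buffer"),
                             channels)
  empties <- stats::setNames(lapply(channels, pick, role = "empty_cell"),
                             channels)
  basis <- build_reference_basis(
    buffer_by_channel = buffers, empty_by_channel = empties,
    donor_ref = pick("donor_ref", donor_ch),
    acceptor_ref_donor_exc = pick("acceptor_ref", donor_ch),
    acceptor_ref_acceptor_exc = pick("acceptor_ref", acceptor_ch))

  is_sample <- roles %in% sample_roles()
  keys <- vapply(spectra, function(s) {
    paste(s$sample_id, s$replicate, sep = "\r")
  }, character(1))
  fits <- list()
  fret_results <- list()
  for (key in unique(keys[is_sample])) {
    idx <- which(keys == key & is_sample)
    ss <- spectra[idx]
    ss_ch <- vapply(ss, `[[`, numeric(1), "excitation_nm")
    if (!all(channels %in% ss_ch)) {
      stop("manifest error: sample '", ss[[1]]$sample_id, "' replicate ",
           ss[[1]]$replicate, " lacks one excitation channel", call. = FALSE)
    }
    s_d <- ss[[match(donor_ch, ss_ch)]]
    s_a <- ss[[match(acceptor_ch, ss_ch)]]
    u_d <- unmix(subtract_buffer(s_d, buffers[[as.character(donor_ch)]]),
                 basis)
    u_a <- unmix(subtract_buffer(s_a, buffers[[as.character(acceptor_ch)]]),
                 basis)
    fits[[paste0(s_d$sample_id, "_rep", s_d$replicate, "_", donor_ch)]] <- u_d
    fits[[paste0(s_a$sample_id, "_rep", s_a$replicate, "_",
                 acceptor_ch)]] <- u_a
    fret_results[[length(fret_results) + 1L]] <-
      compute_efa(u_d, u_a, basis, cal)
  }

  results <- do.call(rbind, lapply(fret_results, function(r) {
    data.frame(sample_id = r$sample_id, replicate = r$replicate,
               role = r$role, efa = r$efa,
               donor_amplitude = r$donor_amplitude_donor_exc,
               acceptor_direct = r$direct_acceptor_donor_exc,
               sensitized = r$sensitized,
               r_squared_donor_exc = r$r_squared[["donor_exc"]],
               r_squared_acceptor_exc = r$r_squared[["acceptor_exc"]],
               qc_flags = paste(r$qc_flags, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  summary_df <- do.call(rbind, lapply(split(results, results$sample_id),
                                      function(g) {
    summarize_replicates(g$efa, group = g$sample_id[[1]])
  }))
  rownames(summary_df) <- NULL
  structure(list(basis = basis, unmix_fits = fits, results = results,
                 summary = summary_df, fret_results = fret_results,
                 calibration = cal),
            class = "fret_experiment")
}

#' @export
print.fret_experiment <- function(x, ...) {
  cat("<fret_experiment>\n")
  cat(sprintf("  cross-talk rho: %.4f\n", x$basis$crosstalk_rho))
  cat("  group summary (EfA %, sample SD, n):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-16s %5.1f  %4.1f  %d\n", s$group[[i]],
                s$mean_efa[[i]], s$sd[[i]], s$n[[i]]))
  }
  invisible(x)
}

#' Compare two sample groups of a fitted experiment
#' @param x A `"fret_experiment"`.
#' @param group_a,group_b Sample ids.
#' @return A [compare_groups()] result.
#' @export
compare_experiment_groups <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "fret_experiment"))
  efa <- function(g) x$results$efa[x$results$sample_id == g]
  compare_groups(efa(group_a), efa(group_b), labels = c(group_a, group_b))
}

# ---- command-line entry points (wrapped by inst/cli/fretunmix.R) -----------

#' Run the unmixing pipeline from a manifest and write report tables
#'
#' Writes `fret_results.tsv` (per replicate), `fret_summary.tsv` (per group),
#' `unmix_amplitudes.tsv`, pairwise `comparisons.tsv` for groups with n >= 2,
#' and `run_log.txt` recording the inputs, calibration and package version.
#'
#' @param manifest Manifest file path.
#' @param out_dir Output directory.
#' @param kappa,r0 Calibration constants (see [fret_calibration()]).
#' @return The `"fret_experiment"`, invisibly.
#' @export
cmd_unmix <- function(manifest, out_dir, kappa = 1.0, r0 = 6.4) {
  cal <- fret_calibration(kappa, r0)
  fit <- fret_analysis(manifest, cal)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(fit$results, "fret_results.tsv")
  wt(fit$summary, "fret_summary.tsv")
  amps <- do.call(rbind, lapply(fit$unmix_fits, function(u) {
    co <- coef(u)
    data.frame(sample_id = u$sample_id, replicate = u$replicate,
               excitation_nm = u$excitation_nm,
               background = co[["background"]],
               donor = if ("donor" %in% names(co)) co[["donor"]] else NA,
               acceptor = co[["acceptor"]], r_squared = u$r.squared,
               residual_mad = u$residual_mad, stringsAsFactors = FALSE)
  }))
  wt(amps, "unmix_amplitudes.tsv")
  groups <- fit$summary$group[fit$summary$n >= 2]
  if (length(groups) >= 2) {
    cmp <- do.call(rbind, utils::combn(groups, 2, function(p) {
      g <- compare_experiment_groups(fit, p[[1]], p[[2]])
      data.frame(group_a = g$group_a, group_b = g$group_b,
                 t_statistic = g$t_statistic, df = g$df,
                 p_value = g$p_value, stars = g$stars,
                 stringsAsFactors = FALSE)
    }, simplify = FALSE))
    wt(cmp, "comparisons.tsv")
  }
  writeLines(c(
    sprintf("fretunmix version: %s",
            as.character(utils::packageVersion("fretunmix"))),
    sprintf("manifest: %s", if (is.character(manifest)) manifest else
      "<in-memory>"),
    sprintf("manifest md5: %s", if (is.character(manifest))
      unname(tools::md5sum(manifest)) else NA),
    sprintf("kappa: %g", kappa),
    sprintf("r0_nm: %g", r0),
    sprintf("crosstalk_rho: %.8g", fit$basis$crosstalk_rho)
  ), file.path(out_dir, "run_log.txt"))
  invisible(fit)
}

#' Convert an EfA percentage to an apparent distance (CLI helper)
#' @param efa_percent Acceptor FRET efficiency in percent, in (0, 100).
#' @param r0 Förster distance in nm.
#' @param quiet Suppress printing.
#' @return Distance in nm, invisibly.
#' @export
cmd_distance <- function(efa_percent, r0 = 6.4, quiet = FALSE) {
  if (!is.finite(efa_percent) || efa_percent <= 0 || efa_percent >= 100) {
    stop("usage error: EfA must be in (0, 100) percent", call. = FALSE)
  }
  r <- efficiency_to_distance(efa_percent / 100, fret_calibration(r0_nm = r0))
  if (!quiet) cat(sprintf("%.1f nm\n", r))
  invisible(r)
}

#' Compute muropeptide composition summaries for a peak table (CLI helper)
#' @param table_path Input peak-area table path.
#' @param out Output TSV path (printed to console when `NULL`).
#' @return The composition data frame, invisibly.
#' @export
cmd_muro <- function(table_path, out = NULL) {
  t <- read_muro_table(table_path)
  comp <- muro_composition_table(t)
  if (is.null(out)) {
    print(comp)
  } else {
    utils::write.table(comp, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(comp)
}

#' Generate a synthetic FRET panel on disk (CLI helper)
#' @param out_dir Output directory.
#' @param kinds Character vector of sample kinds (see
#'   [simulate_pair_spectra()]).
#' @param n_replicates Replicates per sample.
#' @param seed RNG seed.
#' @param ... Passed to [synthetic_panel_config()].
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(out_dir, kinds = c("tandem", "negative", "pair"),
                         n_replicates = 4L, seed = 1L, ...) {
  cfg <- synthetic_panel_config(n_replicates = n_replicates, seed = seed, ...)
  panel <- simulate_panel(lapply(kinds, function(k) list(kind = k)), cfg)
  invisible(write_panel(panel, out_dir))
}
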