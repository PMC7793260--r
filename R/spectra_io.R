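#' Emission spectrum container
#'
#' Constructs a validated fluorescence emission scan: a strictly increasing
#' wavelength axis (nm) with one intensity per wavelength (arbitrary counts),
#' tagged with the excitation channel and its experimental role.
#'
#' @param wavelengths Numeric vector of emission wavelengths in nm, strictly
#'   increasing.
#' @param intensities Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelengths`.
#' @param sample_id Character label identifying the biological sample.
#' @param excitation_nm Excitation wavelength in nm. Must lie below
#'   `min(wavelengths)`: emission is collected red of the excitation line
#'   through a long-pass filter.
#' @param replicate Integer replicate index, `>= 1`.
#' @param role One of `"buffer"`, `"empty_cell"`, `"donor_ref"`,
#'   `"acceptor_ref"`, `"fret_sample"`, `"tandem"`, `"negative"`.
#'
#' @return An object of class `"emission_spectrum"`.
#' @export
emission_spectrum <- function(wavelengths, intensities, sample_id,
                              excitation_nm, replicate = 1L,
                              role = "fret_sample") {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("format error: wavelengths and intensities differ in length",
         call. = FALSE)
  }
  if (length(wavelengths) < 10L) {
    stop("insufficient-data error: fewer than 10 spectral points",
         call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("format error: wavelengths must be strictly increasing",
         call. = FALSE)
  }
  role <- match.arg(role, spectrum_roles())
  excitation_nm <- as.numeric(excitation_nm)
  if (!is.finite(excitation_nm) || excitation_nm >= min(wavelengths)) {
    stop("format error: excitation wavelength must lie below the emission ",
         "window (long-pass collection)", call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) {
    stop("format error: replicate must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      excitation_nm = excitation_nm,
      wavelengths = wavelengths,
      intensities = intensities,
      replicate = replicate,
      role = role
    ),
    class = "emission_spectrum"
  )
}

spectrum_roles <- function() {
  c("buffer", "empty_cell", "donor_ref", "acceptor_ref",
    "fret_sample", "tandem", "negative")
}

#' Roles that are measured FRET samples (present in both channels)
#' @noRd
sample_roles <- function() c("fret_sample", "tandem", "negative")

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "<emission_spectrum> %s  role=%s  exc=%g nm  rep=%d  %d pts [%g-%g nm]\n",
    x$sample_id, x$role, x$excitation_nm, x$replicate,
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# Auto-detect comma vs tab on the first non-comment data line.
detect_delim <- function(lines) {
  data_lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(data_lines)) return(",")
  if (grepl("\t", data_lines[[1]])) "\t" else ","
}

#' Read an emission spectrum from a delimited text file
#'
#' Files are two-column (wavelength nm, intensity) tables, comma- or
#' tab-delimited (auto-detected), with optional `#`-prefixed header lines of
#' the form `# key: value` carrying `sample_id`, `excitation_nm`, `replicate`
#' and `role`. Metadata given in `meta` (e.g. a manifest row) overrides the
#' file header.
#'
#' @param path Path to the spectrum file.
#' @param meta Optional named list or one-row data frame with any of
#'   `sample_id`, `excitation_nm`, `replicate`, `role`.
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path, meta = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  header <- list()
  hdr_lines <- lines[startsWith(trimws(lines), "#")]
  for (h in hdr_lines) {
    h <- sub("^\\s*#\\s*", "", h)
    kv <- regmatches(h, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L) header[[kv[[2]]]] <- trimws(kv[[3]])
  }
  delim <- detect_delim(lines)
  data_lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(data_lines, delim, fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 2L && !any(is.na(suppressWarnings(as.numeric(p[1:2]))))
  }, logical(1))
  if (any(!ok)) {
    stop("format error: malformed rows in ", path, " (lines ",
         paste(which(!ok), collapse = ", "), ")", call. = FALSE)
  }
  wl <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
  it <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))

  if (is.data.frame(meta)) meta <- as.list(meta[1, , drop = FALSE])
  getf <- function(key, default = NULL) {
    if (!is.null(meta[[key]]) && !is.na(meta[[key]])) return(meta[[key]])
    if (!is.null(header[[key]])) return(header[[key]])
    default
  }
  sample_id <- getf("sample_id", tools::file_path_sans_ext(basename(path)))
  exc <- getf("excitation_nm")
  if (is.null(exc)) {
    stop("format error: excitation_nm missing from header and metadata for ",
         path, call. = FALSE)
  }
  emission_spectrum(
    wavelengths = wl, intensities = it,
    sample_id = sample_id,
    excitation_nm = as.numeric(exc),
    replicate = as.integer(getf("replicate", 1L)),
    role = as.character(getf("role", "fret_sample"))
  )
}

#' Write an emission spectrum to a delimited text file
#'
#' The canonical on-disk form: `#`-prefixed metadata header followed by
#' comma-separated `wavelength,intensity` rows. `read_spectrum()` on the
#' output reproduces the spectrum exactly.
#'
#' @param s An [emission_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "emission_spectrum"))
  header <- c(
    sprintf("# sample_id: %s", s$sample_id),
    sprintf("# excitation_nm: %.10g", s$excitation_nm),
    sprintf("# replicate: %d", s$replicate),
    sprintf("# role: %s", s$role)
  )
  rows <- sprintf("%.10g,%.17g", s$wavelengths, s$intensities)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Resample a spectrum onto a regular wavelength grid
#'
#' Linear interpolation onto `seq(start, stop, step)`. The grid must lie
#' within the measured range; no extrapolation is performed. Grid nodes that
#' coincide with original sample points reproduce the original intensities.
#'
#' @param s An [emission_spectrum()].
#' @param grid Numeric `c(start, stop, step)` in nm, or a numeric vector of
#'   target wavelengths.
#' @return A resampled [emission_spectrum()].
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "emission_spectrum"))
  wl_new <- if (length(grid) == 3L && grid[[3]] < grid[[2]] - grid[[1]]) {
    seq(grid[[1]], grid[[2]], by = grid[[3]])
  } else {
    as.numeric(grid)
  }
  if (min(wl_new) < min(s$wavelengths) || max(wl_new) > max(s$wavelengths)) {
    stop("range error: target grid [", min(wl_new), ", ", max(wl_new),
         "] extends beyond measured range [", min(s$wavelengths), ", ",
         max(s$wavelengths), "] nm (no extrapolation)", call. = FALSE)
  }
  it_new <- stats::approx(s$wavelengths, s$intensities, xout = wl_new,
                          method = "linear", ties = "ordered")$y
  emission_spectrum(wl_new, it_new, s$sample_id, s$excitation_nm,
                    s$replicate, s$role)
}

#' Load and validate an experiment manifest
#'
#' A manifest is a delimited table (comma or tab, auto-detected) with one row
#' per scan and columns `path`, `sample_id`, `role`, `excitation_nm`,
#' `replicate`. Validation enforces the per-experiment reference panel: one
#' buffer and one empty-cell scan per excitation channel, a donor-only
#' reference in the donor channel, an acceptor-only reference in both
#' channels, and every FRET sample measured in both channels.
#'
#' @param path Manifest file path. Relative `path` entries are resolved
#'   against the manifest's directory.
#' @return A data frame of class `"fret_manifest"`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  delim <- detect_delim(lines)
  m <- utils::read.table(text = lines, sep = delim, header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  required <- c("path", "sample_id", "role", "excitation_nm", "replicate")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop("manifest error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m$excitation_nm <- as.numeric(m$excitation_nm)
  m$replicate <- as.integer(m$replicate)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  validate_manifest(m)
}

#' @rdname load_manifest
#' @param m A manifest data frame.
#' @export
validate_manifest <- function(m) {
  bad_roles <- setdiff(unique(m$role), spectrum_roles())
  if (length(bad_roles)) {
    stop("manifest error: unknown roles ", paste(bad_roles, collapse = ", "),
         call. = FALSE)
  }
  channels <- sort(unique(m$excitation_nm))
  donor_ch <- channels[[1]]
  for (ch in channels) {
    for (r in c("buffer", "empty_cell")) {
      n <- sum(m$role == r & m$excitation_nm == ch)
      if (n != 1L) {
        stop("manifest error: need exactly one ", r, " scan at excitation ",
             ch, " nm (found ", n, ")", call. = FALSE)
      }
    }
    if (sum(m$role == "acceptor_ref" & m$excitation_nm == ch) < 1L) {
      stop("manifest error: missing acceptor_ref at excitation ", ch, " nm",
           call. = FALSE)
    }
  }
  if (sum(m$role == "donor_ref" & m$excitation_nm == donor_ch) < 1L) {
    stop("manifest error: missing donor_ref at excitation ", donor_ch, " nm",
         call. = FALSE)
  }
  samp <- m[m$role %in% sample_roles(), , drop = FALSE]
  if (nrow(samp)) {
    for (id in unique(samp$sample_id)) {
      chs <- unique(samp$excitation_nm[samp$sample_id == id])
      if (length(setdiff(channels, chs))) {
        stop("manifest error: sample '", id, "' not measured in both ",
             "excitation channels", call. = FALSE)
      }
    }
  }
  class(m) <- c("fret_manifest", "data.frame")
  m
}

#' Write an experiment manifest
#' @param m A manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  utils::write.table(as.data.frame(m)[, c("path", "sample_id", "role",
                                          "excitation_nm", "replicate")],
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
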