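#' Subtract the PBS buffer scan from a sample scan
#'
#' Pointwise subtraction of the buffer (cuvette + PBS) measurement. Negative
#' values are retained — they are noise, not signal — but the result carries a
#' `negative_fraction` attribute and a warning is issued when more than 5% of
#' points go negative.
#'
#' @param sample,buffer [emission_spectrum()] objects on the same wavelength
#'   grid and excitation channel.
#' @return An [emission_spectrum()] of the difference.
#' @export
subtract_buffer <- function(sample, buffer) {
  check_aligned(sample, buffer)
  out <- sample
  out$intensities <- sample$intensities - buffer$intensities
  neg_frac <- mean(out$intensities < 0)
  attr(out, "negative_fraction") <- neg_frac
  if (neg_frac > 0.05) {
    warning(sprintf(
      "%.0f%% of points negative after buffer subtraction for '%s'",
      100 * neg_frac, sample$sample_id), call. = FALSE)
  }
  out
}

#' Subtract the empty-cell (autofluorescence) reference from a fluorophore
#' reference
#'
#' Both inputs must already be buffer-subtracted and on the same grid. The
#' result is clipped at zero: it is destined for shape extraction, where
#' negative intensities are unphysical.
#'
#' @param ref Buffer-subtracted fluorophore reference scan.
#' @param empty_cell Buffer-subtracted empty-cell scan of the same channel.
#' @return An [emission_spectrum()], nonnegative.
#' @export
subtract_background_reference <- function(ref, empty_cell) {
  check_aligned(ref, empty_cell)
  out <- ref
  out$intensities <- pmax(ref$intensities - empty_cell$intensities, 0)
  out
}

check_aligned <- function(a, b) {
  if (a$excitation_nm != b$excitation_nm) {
    stop("alignment error: excitation channels differ (", a$excitation_nm,
         " vs ", b$excitation_nm, " nm)", call. = FALSE)
  }
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(a$wavelengths != b$wavelengths)) {
    stop("alignment error: wavelength grids differ between '", a$sample_id,
         "' and '", b$sample_id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# Extract a unit-norm (Euclidean) component shape from a background-
# subtracted reference scan. The scan is first smoothed with a GCV-tuned
# cubic smoothing spline (emission bands are smooth; rectifying raw noise at
# the zero clip would otherwise put a spurious positive tail into the shape,
# which a strong co-fitted component then leverages into a systematic
# amplitude bias), then clipped at zero and normalized. With noise-free
# input the spline interpolates and the extraction is exact.
unit_shape <- function(s, what) {
  fit <- stats::smooth.spline(s$wavelengths, s$intensities,
                              all.knots = TRUE)
  sm <- stats::predict(fit, s$wavelengths)$y
  noise <- stats::mad(s$intensities - sm)
  v <- pmax(sm, 0)
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm <= 0) {
    stop("degenerate-reference error: ", what, " has no signal after ",
         "background subtraction", call. = FALSE)
  }
  if (max(v) < 3 * noise) {
    stop("weak-reference error: ", what, " peak signal below 3x residual ",
         "noise", call. = FALSE)
  }
  list(shape = v / nrm, norm = nrm)
}

#' Build the per-experiment spectral reference basis
#'
#' From the experiment's reference scans (all already resampled to the common
#' per-channel grids and buffer-subtracted) this derives the component shapes
#' used to unmix every sample:
#'
#' Each shape is extracted by smoothing the background-subtracted reference
#' with a GCV-tuned cubic spline, clipping at zero and normalizing to unit
#' Euclidean norm (smoothing prevents clip-rectified noise from biasing the
#' shape tails; it is exact for noise-free input):
#'
#' * `background_shape` per channel — the empty-cell scan, unit-normalized
#'   (cellular autofluorescence, one free scale factor in the fit);
#' * `donor_shape` — the donor-only (mKO) reference minus empty cell, donor
#'   excitation channel;
#' * `acceptor_shape` per channel — the acceptor-only (mCherry) reference
#'   minus empty cell;
#' * `crosstalk_rho` — the acceptor reference's fitted acceptor amplitude
#'   under donor excitation divided by its fitted amplitude under acceptor
#'   excitation. This calibrates direct (non-FRET) excitation of the acceptor
#'   at the donor excitation wavelength and lets sensitized emission be
#'   isolated arithmetically, since sensitized and directly excited acceptor
#'   emission are spectrally identical.
#'
#' @param buffer_by_channel,empty_by_channel Named lists (names =
#'   excitation wavelength as character) of raw buffer and empty-cell scans.
#' @param donor_ref Donor-only reference scan, donor channel (raw).
#' @param acceptor_ref_donor_exc,acceptor_ref_acceptor_exc Acceptor-only
#'   reference scans in the donor and acceptor excitation channels (raw).
#' @return An object of class `"reference_basis"`.
#' @export
build_reference_basis <- function(buffer_by_channel, empty_by_channel,
                                  donor_ref, acceptor_ref_donor_exc,
                                  acceptor_ref_acceptor_exc) {
  ch_d <- as.character(donor_ref$excitation_nm)
  ch_a <- as.character(acceptor_ref_acceptor_exc$excitation_nm)
  if (ch_d == ch_a) {
    stop("degenerate-reference error: donor and acceptor excitation ",
         "channels are identical", call. = FALSE)
  }

  sub_be <- function(s) {
    ch <- as.character(s$excitation_nm)
    s_b <- subtract_buffer(s, buffer_by_channel[[ch]])
    empty_b <- subtract_buffer(empty_by_channel[[ch]], buffer_by_channel[[ch]])
    subtract_background_reference(s_b, empty_b)
  }
  empty_b <- lapply(empty_by_channel, function(e) {
    ch <- as.character(e$excitation_nm)
    subtract_buffer(e, buffer_by_channel[[ch]])
  })

  bg <- lapply(empty_b, unit_shape, what = "empty-cell reference")
  don <- unit_shape(sub_be(donor_ref), "donor reference")
  acc_d <- unit_shape(sub_be(acceptor_ref_donor_exc),
                      "acceptor reference (donor excitation)")
  acc_a <- unit_shape(sub_be(acceptor_ref_acceptor_exc),
                      "acceptor reference (acceptor excitation)")

  basis <- structure(
    list(
      donor_channel = donor_ref$excitation_nm,
      acceptor_channel = acceptor_ref_acceptor_exc$excitation_nm,
      grid = stats::setNames(
        list(donor_ref$wavelengths, acceptor_ref_acceptor_exc$wavelengths),
        c(ch_d, ch_a)),
      background_shape = lapply(bg, `[[`, "shape"),
      background_norm = vapply(bg, `[[`, numeric(1), "norm"),
      donor_shape = don$shape,
      acceptor_shape = stats::setNames(
        list(acc_d$shape, acc_a$shape), c(ch_d, ch_a)),
      crosstalk_rho = NA_real_
    ),
    class = "reference_basis"
  )

  # rho from the acceptor reference fitted in each channel with its own basis
  amp_d <- coef(unmix(sub_be(acceptor_ref_donor_exc), basis))[["acceptor"]]
  amp_a <- coef(unmix(sub_be(acceptor_ref_acceptor_exc),
                      basis))[["acceptor"]]
  rho <- amp_d / amp_a
  if (!is.finite(rho) || rho <= 0) {
    stop("degenerate-reference error: acceptor cross-talk ratio is not a ",
         "positive finite number (no direct acceptor excitation in the ",
         "donor channel?)", call. = FALSE)
  }
  basis$crosstalk_rho <- rho
  basis$condition_number <- vapply(
    names(basis$acceptor_shape), function(ch) {
      B <- basis_matrix(basis, as.numeric(ch))
      kappa_cond(B)
    }, numeric(1))
  basis
}

#' @export
print.reference_basis <- function(x, ...) {
  cat("<reference_basis>\n")
  cat(sprintf("  donor channel:    %g nm excitation (%d grid pts)\n",
              x$donor_channel,
              length(x$grid[[as.character(x$donor_channel)]])))
  cat(sprintf("  acceptor channel: %g nm excitation (%d grid pts)\n",
              x$acceptor_channel,
              length(x$grid[[as.character(x$acceptor_channel)]])))
  cat(sprintf("  crosstalk rho:    %.4f\n", x$crosstalk_rho))
  if (!is.null(x$condition_number)) {
    cat(sprintf("  basis condition:  %s\n",
                paste(sprintf("%s nm: %.1f", names(x$condition_number),
                              x$condition_number), collapse = ", ")))
  }
  invisible(x)
}

# Column matrix for the given channel: background, donor (donor channel
# only), acceptor.
basis_matrix <- function(basis, excitation_nm) {
  ch <- as.character(excitation_nm)
  if (!ch %in% names(basis$background_shape)) {
    stop("alignment error: no reference basis for excitation ", ch, " nm",
         call. = FALSE)
  }
  cols <- list(background = basis$background_shape[[ch]])
  if (excitation_nm == basis$donor_channel) cols$donor <- basis$donor_shape
  cols$acceptor <- basis$acceptor_shape[[ch]]
  do.call(cbind, cols)
}

kappa_cond <- function(B) {
  d <- svd(B, nu = 0, nv = 0)$d
  if (min(d) <= 0) Inf else max(d) / min(d)
}

#' Unmix a measured spectrum into reference component amplitudes
#'
#' Fits the buffer-subtracted sample spectrum as a nonnegative linear
#' combination of the channel's reference shapes — background, donor (donor
#' channel only) and acceptor — by non-negative least squares:
#' \deqn{\min_{\alpha \ge 0} \| s - B\alpha \|_2.}
#' Nonnegativity reflects that the coefficients are component abundances;
#' it prevents unphysical compensation between the overlapping mKO and
#' mCherry emission bands. Sensitized emission is not a separate column —
#' it is spectrally identical to directly excited acceptor emission and is
#' isolated downstream via the basis cross-talk factor.
#'
#' @param s Buffer-subtracted [emission_spectrum()] on the basis grid.
#' @param basis A [build_reference_basis()] object.
#' @return An object of class `"unmix"` with components `coefficients`
#'   (named nonnegative amplitudes), `fitted.values`, `residuals`,
#'   `r.squared`, `residual_mad` and metadata. Standard `coef()`,
#'   `fitted()`, `residuals()`, `print()`, `summary()` and `plot()` methods
#'   apply.
#' @export
unmix <- function(s, basis) {
  stopifnot(inherits(s, "emission_spectrum"),
            inherits(basis, "reference_basis"))
  ch <- as.character(s$excitation_nm)
  grid <- basis$grid[[ch]]
  if (is.null(grid) || length(grid) != length(s$wavelengths) ||
      any(grid != s$wavelengths)) {
    stop("alignment error: sample '", s$sample_id, "' is not on the basis ",
         "grid for excitation ", ch, " nm", call. = FALSE)
  }
  B <- basis_matrix(basis, s$excitation_nm)
  if (nrow(B) < ncol(B)) {
    stop("underdetermined error: fewer grid points (", nrow(B),
         ") than basis components (", ncol(B), ")", call. = FALSE)
  }
  kap <- kappa_cond(B)
  if (kap > 1e6) {
    stop("collinearity error: basis condition number ",
         format(kap, digits = 3), " exceeds 1e6", call. = FALSE)
  }
  if (kap > 1e4) {
    warning("ill-conditioned basis (condition number ",
            format(kap, digits = 3), ")", call. = FALSE)
  }
  y <- s$intensities
  fit <- nnls_solve(B, y)
  alpha <- stats::setNames(as.numeric(fit$x), colnames(B))
  fitted <- as.numeric(B %*% alpha)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(
    list(
      coefficients = alpha,
      fitted.values = fitted,
      residuals = res,
      r.squared = r2,
      residual_mad = stats::mad(res),
      wavelengths = s$wavelengths,
      observed = y,
      sample_id = s$sample_id,
      excitation_nm = s$excitation_nm,
      replicate = s$replicate,
      role = s$role,
      condition_number = kap
    ),
    class = "unmix"
  )
}

#' @export
print.unmix <- function(x, ...) {
  cat(sprintf("<unmix> %s (exc %g nm, rep %d)\n", x$sample_id,
              x$excitation_nm, x$replicate))
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared: %.5f   residual MAD: %.4g\n",
              x$r.squared, x$residual_mad))
  invisible(x)
}

#' @export
summary.unmix <- function(object, ...) {
  structure(list(
    sample_id = object$sample_id,
    excitation_nm = object$excitation_nm,
    replicate = object$replicate,
    coefficients = object$coefficients,
    r.squared = object$r.squared,
    residual_mad = object$residual_mad,
    n = length(object$residuals),
    condition_number = object$condition_number
  ), class = "summary.unmix")
}

#' @export
print.summary.unmix <- function(x, ...) {
  cat(sprintf("Spectral unmixing fit: %s (excitation %g nm, replicate %d)\n",
              x$sample_id, x$excitation_nm, x$replicate))
  cat(sprintf("%d wavelengths, basis condition number %.2f\n\n",
              x$n, x$condition_number))
  cat("Component amplitudes (nonnegative least squares):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nR-squared: %.5f\nResidual MAD: %.4g\n",
              x$r.squared, x$residual_mad))
  invisible(x)
}

#' Plot an unmixing fit: measured vs fitted spectrum and residuals
#' @param x An `"unmix"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.unmix <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$wavelengths, x$observed, type = "l",
                 xlab = "wavelength (nm)", ylab = "intensity (a.u.)",
                 main = sprintf("%s (exc %g nm)", x$sample_id,
                                x$excitation_nm), ...)
  graphics::lines(x$wavelengths, x$fitted.values, col = 2, lty = 2)
  graphics::legend("topright", c("measured", "fitted"), col = c(1, 2),
                   lty = c(1, 2), bty = "n")
  graphics::plot(x$wavelengths, x$residuals, type = "h",
                 xlab = "wavelength (nm)", ylab = "residual")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
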