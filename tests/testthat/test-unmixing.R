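test_that("buffer subtraction is exact and flags pervasive negativity", {
  n <- 30
  wl <- seq(550, length.out = n)
  buf <- emission_spectrum(wl, rep(20, n), "buffer", 541, role = "buffer")
  band <- 50 * exp(-((wl - 565)^2) / 50)
  s <- emission_spectrum(wl, 20 + band, "s", 541)

  expect_equal(subtract_buffer(buf, buf)$intensities, rep(0, n))
  expect_equal(subtract_buffer(s, buf)$intensities, band)

  below <- emission_spectrum(wl, rep(10, n), "low", 541)
  expect_warning(subtract_buffer(below, buf), "negative")

  other_grid <- emission_spectrum(wl + 5, rep(20, n), "buffer", 541)
  expect_error(subtract_buffer(s, other_grid), "alignment error")
  other_ch <- emission_spectrum(wl + 60, rep(20, n), "buffer", 587)
  expect_error(subtract_buffer(s, other_ch), "alignment error")
})

test_that("empty-cell subtraction clips at zero and recovers an added band", {
  n <- 40
  wl <- seq(600, length.out = n)
  empty <- emission_spectrum(wl, 30 + 0.1 * (wl - 600), "empty", 587,
                             role = "empty_cell")
  band <- 80 * exp(-((wl - 615)^2) / 60)
  ref <- emission_spectrum(wl, empty$intensities + band, "acc", 587,
                           role = "acceptor_ref")
  got <- subtract_background_reference(ref, empty)
  expect_equal(got$intensities, band)
  expect_true(all(subtract_background_reference(empty, ref)$intensities == 0))
})

test_that("zero-noise reference recovery: derived shapes match the
          generator's fluorophore shapes almost perfectly", {
  basis <- exact_basis()
  grid_d <- basis$grid[["541"]]
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(basis$donor_shape,
                   emission_shape(default_donor_model(), grid_d)), 0.999)
  expect_gt(cosine(basis$acceptor_shape[["541"]],
                   emission_shape(default_acceptor_model(), grid_d)), 0.999)
  # cross-talk factor equals the ratio of excitation efficiencies
  expect_equal(basis$crosstalk_rho, 0.25, tolerance = 1e-6)
  expect_true(all(basis$donor_shape >= 0))
  expect_equal(sum(basis$donor_shape^2), 1, tolerance = 1e-12)
  expect_equal(sum(basis$acceptor_shape[["587"]]^2), 1, tolerance = 1e-12)
})

test_that("an acceptor reference with identical response in both channels
          gives crosstalk_rho of 1", {
  cfg <- synthetic_panel_config(
    acceptor = fluorophore_model("flat-excitation acceptor", 610, 22, 2,
                                 relative_excitation = c("541" = 1,
                                                         "587" = 1)),
    grid_donor_exc = c(600, 700, 1), grid_acceptor_exc = c(600, 700, 1),
    noise_sigma = 0, n_replicates = 1, seed = 5)
  # the narrow 600-700 nm grid intentionally truncates both bands; the
  # generator's note about that is expected here
  basis <- suppressMessages(
    fret_analysis(simulate_pair_spectra(cfg, "negative"))$basis)
  expect_equal(basis$crosstalk_rho, 1, tolerance = 1e-9)
})

test_that("an acceptor reference with no signal under donor excitation is a
          degenerate reference", {
  cfg <- synthetic_panel_config(
    acceptor = fluorophore_model("dark-at-donor acceptor", 610, 22, 2,
                                 relative_excitation = c("541" = 0,
                                                         "587" = 1)),
    noise_sigma = 0, n_replicates = 1, seed = 5)
  expect_error(fret_analysis(simulate_pair_spectra(cfg, "negative")),
               "reference")
})

test_that("constructed mixtures are recovered exactly at zero noise", {
  basis <- exact_basis()
  truth <- c(background = 2.0, donor = 3.0, acceptor = 1.5)
  u <- unmix(mixture_spectrum(basis, 541, truth), basis)
  expect_equal(coef(u), truth, tolerance = 1e-9)
  expect_equal(u$r.squared, 1, tolerance = 1e-12)
  expect_equal(fitted(u) + residuals(u), u$observed)

  # strictly positive random amplitudes: identifiability
  set.seed(31)
  for (i in 1:20) {
    a <- c(background = runif(1, 0.5, 5), donor = runif(1, 0.5, 5),
           acceptor = runif(1, 0.5, 5))
    u <- unmix(mixture_spectrum(basis, 541, a), basis)
    expect_equal(coef(u), a, tolerance = 1e-9)
  }
})

test_that("a pure negative component hits the nonnegativity constraint", {
  basis <- exact_basis()
  grid <- basis$grid[["541"]]
  s <- emission_spectrum(grid, -1.0 * basis$donor_shape, "neg", 541)
  u <- unmix(s, basis)
  expect_equal(unname(coef(u)["donor"]), 0)
  expect_true(all(coef(u) >= 0))
  expect_true(is.finite(u$r.squared))
  expect_gt(sum(residuals(u)^2), 0.5)  # most of the signal is unexplainable
})

test_that("unmixing is scale-equivariant", {
  basis <- exact_basis()
  set.seed(13)
  a <- c(background = 1.2, donor = 2.5, acceptor = 0.8)
  s <- mixture_spectrum(basis, 541, a)
  s$intensities <- s$intensities + rnorm(length(s$intensities), 0, 0.01)
  base_coef <- coef(unmix(s, basis))
  for (c_scale in c(0.1, 3, 1000)) {
    s2 <- s
    s2$intensities <- c_scale * s$intensities
    expect_equal(coef(unmix(s2, basis)), c_scale * base_coef,
                 tolerance = 1e-9)
  }
})

test_that("noisy random mixtures agree with the unconstrained oracle within
          sampling error when the oracle is nonnegative", {
  basis <- exact_basis()
  B <- fretunmix:::basis_matrix(basis, 541)
  grid <- basis$grid[["541"]]
  set.seed(99)
  n_interior <- 0
  for (i in 1:200) {
    truth <- runif(3, 0.5, 4)
    peak <- max(B %*% truth)
    y <- as.numeric(B %*% truth) + rnorm(nrow(B), 0, 0.01 * peak)
    u <- unmix(emission_spectrum(grid, y, "m", 541), basis)
    ols <- ols_coef(B, y)
    if (all(ols >= 0)) {
      n_interior <- n_interior + 1
      expect_equal(unname(coef(u)), unname(ols), tolerance = 1e-8)
    }
    # amplitude estimates stay near the truth (noise is 1% of peak)
    expect_lt(max(abs(coef(u) - truth)), 1.5)
  }
  expect_gt(n_interior, 150)
})

test_that("underdetermined and misaligned samples are refused", {
  basis <- exact_basis()
  grid <- basis$grid[["541"]]
  off_grid <- emission_spectrum(grid + 0.5, runif(length(grid)), "x", 541)
  expect_error(unmix(off_grid, basis), "alignment error")
})
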