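make_spec <- function(n = 20, role = "fret_sample", exc = 541, rep = 1) {
  emission_spectrum(seq(550, length.out = n), runif(n, 10, 100),
                    "s1", exc, rep, role)
}

test_that("spectrum validation rejects malformed inputs", {
  expect_error(emission_spectrum(c(550, 551, 551, 553:560), runif(11),
                                 "x", 541),
               "strictly increasing")
  expect_error(emission_spectrum(550:560, runif(5), "x", 541), "length")
  expect_error(emission_spectrum(550:551, runif(2), "x", 541),
               "insufficient-data")
  expect_error(emission_spectrum(550:560, runif(11), "x", 560),
               "below the emission window")
  expect_error(emission_spectrum(550:560, runif(11), "x", 541, replicate = 0),
               "replicate")
  expect_error(emission_spectrum(550:560, runif(11), "x", 541,
                                 role = "nonsense"))
})

test_that("write/read roundtrip is the identity on data and metadata", {
  set.seed(1)
  s <- emission_spectrum(seq(550, 700, by = 1),
                         rexp(151, 1 / 100), "sampleA", 541, 3, "tandem")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_identical(s2$wavelengths, s$wavelengths)
  expect_identical(s2$intensities, s$intensities)
  expect_identical(s2[c("sample_id", "excitation_nm", "replicate", "role")],
                   s[c("sample_id", "excitation_nm", "replicate", "role")])
})

test_that("manifest metadata overrides the file header", {
  s <- make_spec()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, meta = list(role = "buffer", replicate = 5L))
  expect_identical(s2$role, "buffer")
  expect_identical(s2$replicate, 5L)
  expect_identical(s2$sample_id, "s1")  # untouched keys come from the header
})

test_that("files with too few points or garbled rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("550,100.0", "551,102.0"), path)
  expect_error(read_spectrum(path, meta = list(excitation_nm = 541,
                                               role = "buffer")),
               "insufficient-data")
  writeLines(c(sprintf("%d,%g", 550:560, runif(11)), "561,not_a_number"),
             path)
  expect_error(read_spectrum(path, meta = list(excitation_nm = 541)),
               "malformed")
  writeLines(c("550,1", "551,2", "551,2.5", sprintf("%d,1", 552:560)), path)
  expect_error(read_spectrum(path, meta = list(excitation_nm = 541)),
               "strictly increasing")
})

test_that("tab-delimited files are auto-detected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# excitation_nm: 541", sprintf("%d\t%g", 550:569, 1:20)),
             path)
  s <- read_spectrum(path)
  expect_equal(s$intensities, as.numeric(1:20))
})

test_that("resampling is exact for affine intensity profiles and the
          identity on the native grid", {
  wl <- seq(550, 700, by = 2)
  s <- emission_spectrum(wl, 2 * wl + 7, "lin", 541)
  fine <- resample_to_grid(s, c(550, 700, 1))
  expect_equal(fine$intensities, 2 * fine$wavelengths + 7)

  same <- resample_to_grid(fine, c(550, 700, 1))
  expect_identical(same$intensities, fine$intensities)
})

test_that("resampling roundtrip preserves values at original nodes and
          refuses to extrapolate", {
  set.seed(2)
  wl <- seq(550, 700, by = 1)
  y <- 100 * exp(-((wl - 600)^2) / 800)
  s <- emission_spectrum(wl, y, "smooth", 541)
  back <- resample_to_grid(resample_to_grid(s, c(550, 700, 0.5)),
                           c(550, 700, 1))
  expect_equal(back$intensities, y, tolerance = 1e-12)
  expect_error(resample_to_grid(s, c(540, 700, 1)), "range error")
})

test_that("manifest validation enforces the reference panel and channel
          pairing", {
  rows <- function(...) do.call(rbind, lapply(list(...), as.data.frame))
  entry <- function(id, role, exc, rep = 1)
    list(path = "x.csv", sample_id = id, role = role, excitation_nm = exc,
         replicate = rep)
  base <- rows(entry("buffer", "buffer", 541),
               entry("buffer", "buffer", 587),
               entry("empty", "empty_cell", 541),
               entry("empty", "empty_cell", 587),
               entry("don", "donor_ref", 541),
               entry("acc", "acceptor_ref", 541),
               entry("acc", "acceptor_ref", 587),
               entry("s1", "fret_sample", 541),
               entry("s1", "fret_sample", 587))
  expect_s3_class(validate_manifest(base), "fret_manifest")

  expect_error(validate_manifest(base[base$role != "acceptor_ref" |
                                        base$excitation_nm != 587, ]),
               "acceptor_ref at excitation 587")
  expect_error(validate_manifest(base[-which(base$role == "donor_ref"), ]),
               "donor_ref")
  expect_error(validate_manifest(base[-nrow(base), ]),
               "both excitation channels")
  dup <- rbind(base, base[1, ])
  expect_error(validate_manifest(dup), "exactly one buffer")
})

test_that("a generator-emitted manifest loads back with all sample ids", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_panel_config(n_replicates = 2, noise_sigma = 0, seed = 3)
  panel <- simulate_panel(list(list(kind = "tandem"),
                               list(kind = "negative"),
                               list(kind = "pair", sample_id = "p1"),
                               list(kind = "pair", sample_id = "p2")), cfg)
  mpath <- write_panel(panel, dir)
  m <- load_manifest(mpath)
  samp <- m[m$role %in% c("tandem", "negative", "fret_sample"), ]
  expect_setequal(unique(samp$sample_id),
                  c("tandem", "negative", "p1", "p2"))
  s <- read_spectrum(m$path[[1]], m[1, ])
  expect_s3_class(s, "emission_spectrum")
})
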