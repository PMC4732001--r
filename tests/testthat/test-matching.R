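make_fake_fragset <- function(masses, bdes) {
  # hand-built fragment_set with the given neutral masses/energies
  frs <- Map(function(m, b, i) {
    list(atoms = i, bonds = integer(0), bde = b, depth = 1L, mass = m,
         matchable = TRUE)
  }, masses, bdes, seq_along(masses))
  structure(list(structure = NULL, fragments = unname(frs),
                 tree_depth = 1L), class = "fragment_set")
}

test_that("mass tolerance is additive in ppm and Da", {
  s <- match_settings(5, 0.001)
  expect_equal(mass_tolerance(200, s), 0.002)
  expect_equal(mass_tolerance(100, s), 0.0015)
  expect_equal(mass_tolerance(123.4, match_settings(0, 0)), 0)
})

test_that("theoretical ion m/z applies adduct, electron and hydrogen shifts", {
  expect_equal(theoretical_ion_mz(100, "[M+H]+", 0L), 101.00728,
               tolerance = 1e-7)
  expect_equal(theoretical_ion_mz(100, "[M-H]-", 0L), 98.99272,
               tolerance = 1e-7)
  m <- 317.1234
  expect_equal(theoretical_ion_mz(m, "[M+H]+", 0L) -
                 theoretical_ion_mz(m, "[M-H]-", 0L),
               2 * proton_mass(), tolerance = 1e-12)
  expect_equal(theoretical_ion_mz(100, "[M+H]+", 1L) -
                 theoretical_ion_mz(100, "[M+H]+", 0L),
               1.0078250319, tolerance = 1e-12)
  expect_error(precursor_type("[M+2H]2+"), "unsupported")
})

test_that("each peak gets at most one fragment, preferring the lowest energy", {
  fs <- make_fake_fragset(c(100, 100.0001), c(696, 348))
  mz <- theoretical_ion_mz(100, "[M+H]+", 0L)
  spec <- ms2_spectrum(mz, 999, neutral_mass = 200)
  asg <- match_peaks(spec, fs, match_settings(5, 0.001, 0L))
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$bde, 348)
  expect_equal(asg$h_shift, 0L)
})

test_that("peaks outside tolerance stay unassigned; exact peaks match at shift 0", {
  fs <- make_fake_fragset(c(80, 120), c(348, 400))
  hit <- theoretical_ion_mz(80, "[M+H]+", 0L)
  spec <- ms2_spectrum(c(hit, 150.5), c(500, 100), neutral_mass = 200)
  asg <- match_peaks(spec, fs, match_settings(5, 0.001))
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$h_shift, 0L)
  expect_equal(asg$fragment_mass, 80)
})

test_that("hydrogen shifts widen the reachable peaks", {
  fs <- make_fake_fragset(100, 348)
  mz <- theoretical_ion_mz(100, "[M+H]+", 1L)
  spec <- ms2_spectrum(mz, 10, neutral_mass = 200)
  expect_equal(nrow(match_peaks(spec, fs, match_settings(5, 0.001, 0L))), 0L)
  asg <- match_peaks(spec, fs, match_settings(5, 0.001, c(-1L, 0L, 1L)))
  expect_equal(asg$h_shift, 1L)
})

test_that("matching is permutation-invariant and monotone in the tolerance", {
  r <- toy_record("TRZ_TERB")
  cfg <- simulation_config(seed = 11, n_noise_peaks = 4L)
  spec <- simulate_spectrum(r, cfg)
  fs <- generate_fragments(r$structure, 2L)

  perm <- sample(nrow(spec$peaks))
  spec2 <- ms2_spectrum(spec$peaks$mz[perm], spec$peaks$intensity[perm],
                        neutral_mass = spec$neutral_mass)
  a1 <- match_peaks(spec, fs)
  a2 <- match_peaks(spec2, fs)
  expect_equal(a1, a2)
  expect_lte(nrow(a1), nrow(spec$peaks))

  wide <- nrow(match_peaks(spec, fs, match_settings(10, 0.002)))
  narrow <- nrow(match_peaks(spec, fs, match_settings(1, 0.0001)))
  expect_lte(narrow, nrow(a1))
  expect_lte(nrow(a1), wide)
})

test_that("peak list files are parsed with comments and validated", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fragment peaks", "96.0444 532.1", "132.0215 100"), tmp)
  spec <- read_peaklist(tmp, neutral_mass = 229.1094)
  expect_equal(nrow(spec$peaks), 2L)
  expect_equal(spec$peaks$mz, c(96.0444, 132.0215))
  writeLines(c("96.0444 532.1", "oops"), tmp)
  expect_error(read_peaklist(tmp, neutral_mass = 1), "malformed")
  expect_error(ms2_spectrum(c(100, -5), c(1, 1), neutral_mass = 1),
               "non-positive")
})
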