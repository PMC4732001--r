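test_that("the toy library is deterministic and covers the needed cases", {
  lib1 <- make_toy_library()
  lib2 <- make_toy_library()
  expect_identical(candidate_ids(lib1), candidate_ids(lib2))
  masses <- vapply(lib1, `[[`, numeric(1), "mass")
  expect_true(any(duplicated(round(masses, 6))))  # exact-mass isomer groups
  expect_true(any(!vapply(lib1, function(r) is_connected(r$structure),
                          logical(1))))           # one salt
  expect_gte(length(lib1), 30L)
})

test_that("zero-jitter, zero-noise spectra match their own fragments exactly", {
  truth <- toy_record("SUL_MES")
  cfg <- simulation_config(seed = 4, n_noise_peaks = 0L, mz_jitter_sd = 0)
  spec <- simulate_spectrum(truth, cfg)
  fs <- generate_fragments(truth$structure, cfg$tree_depth)
  asg <- match_peaks(spec, fs)
  expect_equal(nrow(asg), nrow(spec$peaks))
  expect_true(all(asg$h_shift == 0L))
  # signal masses are rounded to 1e-6 Da when sampled
  expect_true(all(abs(asg$theoretical_mz - asg$mz) < 1e-5))
})

test_that("small jitter stays within the default matching tolerance", {
  truth <- toy_record("TRZ_SEC")
  cfg <- simulation_config(seed = 8, n_noise_peaks = 0L,
                           mz_jitter_sd = 0.0002)
  spec <- simulate_spectrum(truth, cfg)
  fs <- generate_fragments(truth$structure, cfg$tree_depth)
  asg <- match_peaks(spec, fs)
  expect_equal(nrow(asg), nrow(spec$peaks))
})

test_that("spectrum simulation is reproducible for a fixed seed", {
  truth <- toy_record("TRZ_TERB")
  cfg <- simulation_config(seed = 21)
  s1 <- simulate_spectrum(truth, cfg)
  s2 <- simulate_spectrum(truth, cfg)
  expect_identical(s1$peaks, s2$peaks)
  s3 <- simulate_spectrum(truth, simulation_config(seed = 22))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("decoys preserve the molecular formula with distinct skeleta", {
  truth <- toy_record("TRZ_TERB")
  decoys <- make_decoys(truth, 8L, seed = 2)
  expect_gte(length(decoys), 6L)
  target <- format(truth$formula)
  for (d in decoys) {
    expect_equal(format(d$formula), target)
    expect_true(is_connected(d$structure))
  }
  blocks <- c(inchikey_first_block(truth$structure),
              candidate_first_blocks(decoys))
  expect_equal(anyDuplicated(blocks), 0L)
  expect_identical(candidate_ids(make_decoys(truth, 8L, seed = 2)),
                   candidate_ids(decoys))
})

test_that("noiseless RT training recovers the true line exactly", {
  lib <- make_toy_library()
  tr <- simulate_rt_training(lib, true_a = 0.35, true_b = -1,
                             noise_sd = 0, n = 12, seed = 5)
  m <- fit_rt_model(tr$rt, tr$logp)
  expect_equal(coef(m), c(a = 0.35, b = -1), tolerance = 1e-9)
  tr2 <- simulate_rt_training(lib, true_a = 0.35, true_b = -1,
                              noise_sd = 0, n = 12, seed = 5)
  expect_identical(tr, tr2)
})

test_that("noisy RT training recovers the slope within 3 standard errors", {
  lib <- make_toy_library()
  for (seed in 1:20) {
    tr <- simulate_rt_training(lib, true_a = 0.35, true_b = -1,
                               noise_sd = 0.3, n = 50, seed = seed)
    fit <- stats::lm(logp ~ rt, data = tr)
    a_hat <- stats::coef(fit)[["rt"]]
    se <- summary(fit)$coefficients["rt", "Std. Error"]
    expect_lt(abs(a_hat - 0.35), 3 * se)
  }
})

test_that("identification cases write valid files for the real readers", {
  truth <- toy_record("SUL_IPR")
  cfg <- simulation_config(seed = 9, n_noise_peaks = 2L)
  case <- make_identification_case(truth, 5L, cfg)
  dir <- withr::local_tempdir()
  tr <- simulate_rt_training(make_toy_library(), noise_sd = 0, n = 10,
                             seed = 9)
  paths <- write_fixture_files(case, dir,
                               rt_training = data.frame(rt = tr$rt,
                                                        logp = tr$logp))
  spec <- read_peaklist(paths$peaklist, neutral_mass = truth$mass)
  expect_equal(nrow(spec$peaks), nrow(case$spectrum$peaks))
  cands <- read_candidates(paths$candidates)
  expect_setequal(candidate_ids(cands), candidate_ids(case$candidates))
  sus <- read_suspect_list(paths$suspects)
  expect_equal(sus, inchikey_first_block(truth$structure))
  rt <- read_rt_training(paths$rt_training, logp_column = "UserLogP")
  expect_equal(nrow(rt), 10L)
  # reference counts boost the truth
  refs <- vapply(cands, function(r) {
    as.numeric(r$properties$ReferenceCount)
  }, numeric(1))
  expect_equal(candidate_ids(cands)[which.max(refs)], case$truth_id)
})
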