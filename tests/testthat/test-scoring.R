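fake_assignments <- function(mz, intensity, bde) {
  data.frame(peak = seq_along(mz), mz = mz, intensity = intensity,
             fragment = seq_along(mz), h_shift = rep(0L, length(mz)),
             theoretical_mz = mz, bde = bde, fragment_mass = mz)
}

test_that("fragmenter score follows the relative mass/intensity/energy formula", {
  w <- weight_config()
  empty <- fake_assignments(numeric(0), numeric(0), numeric(0))
  spec <- ms2_spectrum(100, 10, neutral_mass = 200)
  expect_equal(fragmenter_score(empty, spec, w), 0)

  # unit inputs: RelMass = 1, RelInt = 1, sum BDE = 1 -> score 1
  prec <- theoretical_ion_mz(200, "[M+H]+", 0L)
  spec1 <- ms2_spectrum(prec, 555, neutral_mass = 200)
  a1 <- fake_assignments(prec, 555, 1)
  expect_equal(fragmenter_score(a1, spec1, w), 1, tolerance = 1e-12)

  # RelMass 0.5, RelInt 1, BDE 348 with default exponents
  spec2 <- ms2_spectrum(prec / 2, 555, neutral_mass = 200)
  a2 <- fake_assignments(prec / 2, 555, 348)
  expect_equal(fragmenter_score(a2, spec2, w),
               0.5^1.84 / 348^0.47, tolerance = 1e-12)
})

test_that("fragmenter score equals an independent re-evaluation on random inputs", {
  w <- weight_config()
  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    prec_neutral <- runif(1, 150, 400)
    prec <- theoretical_ion_mz(prec_neutral, "[M+H]+", 0L)
    mz <- sort(runif(n, 50, prec))
    int <- runif(n, 1, 1000)
    bde <- runif(n, 200, 2000)
    spec <- ms2_spectrum(mz, int, neutral_mass = prec_neutral)
    asg <- fake_assignments(mz, int, bde)
    got <- fragmenter_score(asg, spec, w)
    want <- oracle_fragmenter_score(asg, prec, max(int))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("normalization maps to [0,1] with a zero-max guard", {
  expect_equal(normalize_terms(c(2, 1, 0)), c(1, 0.5, 0))
  expect_equal(normalize_terms(c(0, 0)), c(0, 0))
  expect_equal(normalize_terms(7), 1)
  expect_error(normalize_terms(c(1, -1)), "non-negative")
})

test_that("final score is the weighted sum, linear and order-invariant", {
  w <- weight_config(c(A = 1))
  expect_equal(combine_final(cbind(A = 0.7), w), 0.7)
  w2 <- weight_config(c(A = 1, B = 1))
  expect_equal(combine_final(cbind(A = 1, B = 0.5), w2), 1.5)
  w3 <- weight_config(c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(combine_final(cbind(A = 0.3, B = 0.4, C = 0.2), w3), 0.31)
  # order invariance
  expect_equal(combine_final(cbind(C = 0.2, A = 0.3, B = 0.4), w3), 0.31)
  # linearity in each term
  m <- cbind(A = 0.2, B = 0.1, C = 0.4)
  m2 <- m; m2[, "B"] <- m[, "B"] + 0.25
  expect_equal(combine_final(m2, w3) - combine_final(m, w3), 0.3 * 0.25)
  expect_warning(combine_final(cbind(A = 1), w2), "missing")
  expect_error(weight_config(c(A = -1)), "negative")
})

test_that("substructure counting is binary per pattern", {
  pats <- c("N[CH2][CH3]", "NCCCC", "NC(C)CC", "NC(C)(C)C")
  # triethazine carries three ethylamino occurrences but scores 1
  expect_equal(substructure_match_count(toy_record("TRZ_TRIE")$structure,
                                        pats), 1L)
  expect_equal(substructure_match_count(toy_record("TRZ_TERB")$structure,
                                        character(0)), 0L)
  expect_error(substructure_match_count("CCO", "not[a[smarts"),
               "invalid SMARTS")
})

test_that("inclusion and exclusion scores normalize match counts", {
  counts <- c(2L, 0L, 1L)
  expect_equal(inclusion_score(counts), c(1, 0, 0.5))
  expect_equal(inclusion_score(c(0L, 0L)), c(0, 0))
  expect_equal(exclusion_score(c(0L, 2L), n = 2), c(1, 0))
  expect_equal(exclusion_score(c(2L, 2L), n = 2), c(0, 0))
})

test_that("combined reference score sums selected sources and normalizes", {
  props <- data.frame(PNP = c(3, 10), PPC = c(0, 5))
  r <- combined_reference_score(props, "PNP")
  expect_equal(r$raw, c(3, 10))
  expect_equal(r$score, c(0.3, 1))
  both <- combined_reference_score(props, c("PNP", "PPC"))
  expect_equal(both$raw, c(3, 15))
  # missing columns count as zero; all-zero lists stay zero
  z <- combined_reference_score(data.frame(PNP = c(0, 0)), c("PNP", "PPC"))
  expect_equal(z$score, c(0, 0))
  expect_error(combined_reference_score(props, character(0)), "empty")
})

test_that("suspect scoring flags listed first blocks", {
  blocks <- inchikey_first_block(c("CCO", "CC(C)O"))
  expect_equal(suspect_score(blocks, blocks[1]), c(1L, 0L))
  expect_equal(suspect_score(blocks, character(0)), c(0L, 0L))
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# suspects", inchikey("CCO"), blocks[2], "", "short"), tmp)
  expect_warning(sus <- read_suspect_list(tmp), "malformed")
  expect_setequal(sus, blocks)
})

test_that("RT model fitting matches the normal-equations solution", {
  m <- suppressWarnings(fit_rt_model(1:3, 1:3))
  expect_equal(coef(m), c(a = 1, b = 0), tolerance = 1e-12)

  set.seed(99)
  for (i in 1:5) {
    rt <- runif(20, 1, 20)
    logp <- 0.3 * rt - 1 + rnorm(20, 0, 0.4)
    m <- fit_rt_model(rt, logp)
    expect_equal(coef(m), oracle_ols(rt, logp), tolerance = 1e-10)
  }

  expect_error(fit_rt_model(1, 1), "at least two")
  expect_error(suppressWarnings(fit_rt_model(c(2, 2, 2), 1:3)), "singular")
  expect_warning(fit_rt_model(1:5, c(1, 2, 2.5, 4, 5)), "ten data points")
})

test_that("retention score is a Gaussian density in the logP deviation", {
  expect_equal(rt_score_density(0, 0, 1.5), 1 / (1.5 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(rt_score_density(3, 1, 1.5), rt_score_density(1, 3, 1.5))
  d <- rt_score_density(3.17, c(3.17, 2.5, 1.5, 0.5), 1.5)
  expect_true(all(diff(d) < 0))  # strictly decreasing in |deviation|
  m <- suppressWarnings(fit_rt_model(1:3, 1:3, sigma = 1.5))
  expect_equal(rt_score(m, 2, 2), 1 / (1.5 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_warning(out <- rt_score_density(2, c(1, NA), 1.5), "without logP")
  expect_equal(out[2], 0)
})

test_that("user score columns are validated and normalized", {
  df <- data.frame(Identifier = c("a", "b"), UserLogP = c(2, 4),
                   CFM = c(0.1, 0.2))
  norm <- attach_user_scores(df, c("UserLogP", "CFM"))
  expect_equal(norm[, "UserLogP"], c(0.5, 1))
  expect_equal(attr(norm, "raw")[, "CFM"], c(0.1, 0.2))
  expect_error(attach_user_scores(df, "Missing"), "Missing")
  df$bad <- c("1.5", "oops")
  expect_error(attach_user_scores(df, "bad"), "row 2")
})

test_that("normalized terms lie in [0,1] and one candidate attains the maximum", {
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(2:30, 1), 0, 100)
    nv <- normalize_terms(v)
    expect_true(all(nv >= 0 & nv <= 1))
    expect_equal(max(nv), 1)
  }
})
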