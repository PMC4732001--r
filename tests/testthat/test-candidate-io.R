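write_demo_csv <- function(path) {
  df <- data.frame(
    Identifier = c("CAND1", "CAND2", "BROKEN"),
    InChI = c(structure_inchi(parse_structure("CCO")),
              structure_inchi(parse_structure("CC(C)O")),
              "InChI=1S/garbage"),
    ChemSpiderReferenceCount = c(94L, 15L, 3L),
    UserLogP = c(1.2, 0.8, 0.1))
  utils::write.csv(df, path, row.names = FALSE)
}

test_that("CSV candidate databases load with properties, skipping bad rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(tmp)
  expect_warning(cs <- read_candidates(tmp), "BROKEN")
  expect_equal(candidate_ids(cs), c("CAND1", "CAND2"))
  expect_equal(cs[[1]]$properties$ChemSpiderReferenceCount, 94L)
  expect_equal(format(cs[[1]]$formula), "C2H6O")
  writeLines("Identifier,InChI", tmp)
  expect_error(read_candidates(tmp), "no valid candidate")
  expect_error(read_candidates("/nonexistent/db.csv"), "not found")
})

test_that("mass selection window is symmetric and inclusive; formula/id modes work", {
  lib <- make_toy_library()
  target <- 229.1089
  sel <- select_candidates(lib, mass = target, ppm = 5)
  expect_setequal(candidate_ids(sel),
                  c("TRZ_TERB", "TRZ_PROP", "TRZ_SEC", "TRZ_TRIE",
                    "TRZ_NBUT"))
  # half-width ~ 0.001146 Da: a mass at 229.1105 falls outside
  half <- target * 5e-6
  fake <- candidate_set(list(
    list(id = "IN", structure = parse_structure("CCO"),
         mass = target + half),          # boundary: inclusive
    list(id = "OUT", structure = parse_structure("CCC"),
         mass = 229.1105)))
  expect_equal(candidate_ids(select_candidates(fake, mass = target)), "IN")

  expect_setequal(
    candidate_ids(select_candidates(lib, formula = "C9H12O3S")),
    c("SUL_MES", "SUL_IPR", "SUL_NPR", "SUL_ETS"))
  expect_equal(candidate_ids(select_candidates(lib, ids = c("ETOH"))),
               "ETOH")
  expect_error(select_candidates(lib, mass = 1, formula = "CH4"),
               "exactly one")
})

test_that("results round-trip through CSV and SDF", {
  lib <- make_toy_library()
  recs <- unclass(lib[candidate_ids(lib) %in% c("ETOH", "PHENOL", "TOLUENE")])
  recs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    r$score_terms_raw <- list(FragmenterScore = c(3, 1, 2)[i])
    r$score_terms <- list(FragmenterScore = c(1, 1 / 3, 2 / 3)[i])
    r$final_score <- c(1, 1 / 3, 2 / 3)[i]
    r
  })
  scored <- candidate_set(recs)
  tab <- results_table(scored)
  expect_equal(tab$Rank, 1:3)
  expect_equal(tab$Score, sort(tab$Score, decreasing = TRUE))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, csv, "CSV")
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(back$Identifier, tab$Identifier)
  expect_equal(back$Score, tab$Score, tolerance = 1e-9)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_results(tab, sdf, "SDF")
  reread <- read_candidates(sdf, format = "SDF")
  expect_equal(candidate_ids(reread), tab$Identifier)
  expect_equal(
    vapply(reread, function(r) inchikey_first_block(r$structure),
           character(1)),
    inchikey_first_block(tab$SMILES))
})

test_that("ranks count strictly greater scores and handle ties pessimistically upstream", {
  lib <- make_toy_library()
  recs <- unclass(lib[candidate_ids(lib) %in% c("ETOH", "PHENOL", "TOLUENE")])
  for (i in seq_along(recs)) {
    recs[[i]]$score_terms_raw <- list()
    recs[[i]]$score_terms <- list()
    recs[[i]]$final_score <- c(0.9, 0.9, 0.5)[i]
  }
  tab <- results_table(candidate_set(recs))
  expect_equal(tab$Rank, c(1L, 1L, 3L))
})

test_that("parameter files parse with defaults, overrides and validation", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# minimal configuration",
    "PeakListPath = peaks.txt",
    "LocalDatabasePath = db.csv",
    "NeutralPrecursorMass = 229.1089",
    "SampleName = run7"
  ), tmp)
  expect_warning(p <- read_parameters(tmp), "SampleName")
  expect_s3_class(p, "parameter_set")
  expect_equal(p$MaximumTreeDepth, 2)
  expect_equal(p$FragmentPeakMatchRelativeMassDeviation, 5)
  expect_equal(p$FragmentPeakMatchAbsoluteMassDeviation, 0.001)
  expect_equal(p$ScoreTerms, "FragmenterScore")

  p2 <- suppressWarnings(
    read_parameters(tmp, overrides = list(MaximumTreeDepth = "3")))
  expect_equal(p2$MaximumTreeDepth, 3)

  writeLines(c("PeakListPath = peaks.txt",
               "LocalDatabasePath = db.csv"), tmp)
  expect_error(read_parameters(tmp), "precursor")
  writeLines(c("PeakListPath = peaks.txt",
               "LocalDatabasePath = db.csv",
               "NeutralPrecursorMass = 229.1089",
               "NeutralPrecursorMolecularFormula = C9H16ClN5"), tmp)
  expect_error(read_parameters(tmp), "conflicting")
  expect_error(parameter_set(PeakListPath = "x"), "mandatory")
  expect_error(
    parameter_set(PeakListPath = "x", LocalDatabasePath = "y",
                  NeutralPrecursorMass = 1,
                  ScoreTerms = c("A", "B"), ScoreWeights = 1),
    "differ in length")
})

test_that("online database types are declared but resolve to a stub", {
  p <- parameter_set(PeakListPath = "x", DatabaseType = "PubChem",
                     NeutralPrecursorMass = 229.1089)
  expect_error(run_pipeline(p), "network retrieval")
})
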