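# Synthetic data generation: a toy structure library, simulated spectra,
# formula-preserving decoy candidates, synthetic retention-time training
# sets and reference counts. Everything is seeded so each stage is
# reproducible in isolation; fixtures can be written out in the exact
# external formats the pipeline readers consume.

.derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage) %% 2147483647)
}

.TOY_LIBRARY <- list(
  c("TRZ_TERB", "terbutylazine", "CCNc1nc(Cl)nc(NC(C)(C)C)n1"),
  c("TRZ_PROP", "propazine", "CC(C)Nc1nc(Cl)nc(NC(C)C)n1"),
  c("TRZ_SEC", "secbutylazine", "CCNc1nc(Cl)nc(NC(C)CC)n1"),
  c("TRZ_TRIE", "triethazine", "CCNc1nc(Cl)nc(N(CC)CC)n1"),
  c("TRZ_NBUT", "n-butylazine", "CCCCNc1nc(Cl)nc(NCC)n1"),
  c("SUL_MES", "mesitylenesulfonic acid", "Cc1cc(C)c(S(=O)(=O)O)c(C)c1"),
  c("SUL_IPR", "4-isopropylbenzenesulfonic acid",
    "CC(C)c1ccc(cc1)S(=O)(=O)O"),
  c("SUL_NPR", "4-propylbenzenesulfonic acid", "CCCc1ccc(cc1)S(=O)(=O)O"),
  c("SUL_ETS", "ethyl p-toluenesulfonate", "CCOS(=O)(=O)c1ccc(C)cc1"),
  c("SALT_NAOAC", "sodium acetate", "[Na+].CC([O-])=O"),
  c("ETOH", "ethanol", "CCO"),
  c("PROPANE", "propane", "CCC"),
  c("BENZENE", "benzene", "c1ccccc1"),
  c("TOLUENE", "toluene", "Cc1ccccc1"),
  c("PHENOL", "phenol", "Oc1ccccc1"),
  c("ANILINE", "aniline", "Nc1ccccc1"),
  c("PYRIDINE", "pyridine", "c1ccncc1"),
  c("FURAN", "furan", "c1ccoc1"),
  c("THIOPHENE", "thiophene", "c1ccsc1"),
  c("ACETONE", "acetone", "CC(C)=O"),
  c("ACOH", "acetic acid", "CC(O)=O"),
  c("GLYCINE", "glycine", "NCC(O)=O"),
  c("ALA_R", "(R)-alanine", "C[C@H](N)C(O)=O"),
  c("ALA_S", "(S)-alanine", "C[C@@H](N)C(O)=O"),
  c("BUOH1", "butan-1-ol", "CCCCO"),
  c("BUOH2", "butan-2-ol", "CC(O)CC"),
  c("TBUOH", "2-methylpropan-2-ol", "CC(C)(O)C"),
  c("ETHER", "diethyl ether", "CCOCC"),
  c("PROPAC", "propanoic acid", "CCC(O)=O"),
  c("MEOAC", "methyl acetate", "COC(C)=O"),
  c("XYL_O", "o-xylene", "Cc1ccccc1C"),
  c("XYL_M", "m-xylene", "Cc1cccc(C)c1"),
  c("XYL_P", "p-xylene", "Cc1ccc(C)cc1"),
  c("CLBENZ", "chlorobenzene", "Clc1ccccc1")
)

#' Toy structure library
#'
#' A deterministic library of small molecules (most under a dozen heavy
#' atoms) covering the situations the pipeline must handle: isomer groups
#' sharing an exact mass (triazine isobars, butanols, xylenes), a
#' stereoisomer pair, sulfonic acids and esters for substructure filters,
#' and one salt for the unconnected filter.
#'
#' @return A `candidate_set`; each record's `properties` carry `Name` and
#'   `SMILES`.
#' @export
make_toy_library <- function() {
  candidate_set(lapply(.TOY_LIBRARY, function(row) {
    list(id = row[1],
         structure = parse_structure(row[3], id = row[1]),
         properties = list(Name = row[2], SMILES = row[3]))
  }))
}

#' Simulation configuration
#'
#' Settings of the synthetic spectrum and evidence generator.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param tree_depth Fragmentation depth used to build signal peaks.
#' @param n_signal_peaks Number of true fragment peaks sampled.
#' @param n_noise_peaks Number of random noise peaks appended.
#' @param mz_jitter_sd Gaussian m/z jitter of signal peaks in Da (kept well
#'   below the default matching tolerance).
#' @param intensity_range Uniform intensity range.
#' @param rt_true `c(a, b)` of the true retention model `logP = a*RT + b`.
#' @param rt_noise_sd Gaussian noise (logP units) applied when inverting
#'   the true line to draw training retention times.
#' @param ref_boost Multiplier applied to the mean decoy reference count to
#'   set the correct candidate's count.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, tree_depth = 2L,
                              n_signal_peaks = 8L, n_noise_peaks = 3L,
                              mz_jitter_sd = 0.0002,
                              intensity_range = c(100, 1000),
                              rt_true = c(a = 0.35, b = -1),
                              rt_noise_sd = 0.3, ref_boost = 5) {
  structure(list(seed = as.integer(seed), tree_depth = as.integer(tree_depth),
                 n_signal_peaks = as.integer(n_signal_peaks),
                 n_noise_peaks = as.integer(n_noise_peaks),
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_range = intensity_range, rt_true = rt_true,
                 rt_noise_sd = rt_noise_sd, ref_boost = ref_boost),
            class = "simulation_config")
}

#' Simulate an MS/MS spectrum from a known structure
#'
#' Fragments the structure at the configured tree depth, samples distinct
#' fragment neutral masses as signal peaks (precursor ion type applied,
#' Gaussian m/z jitter, uniform intensities) and appends noise peaks at
#' uniform random m/z below the precursor while avoiding windows around any
#' theoretical fragment ion. The sampled ground-truth fragment masses are
#' attached as attribute `"ground_truth"`.
#'
#' @param truth A candidate record (list with `structure` and `mass`).
#' @param cfg A `simulation_config`.
#' @param type Precursor ion type name.
#' @return An `ms2_spectrum`.
#' @export
simulate_spectrum <- function(truth, cfg = simulation_config(),
                              type = "[M+H]+") {
  set.seed(.derive_seed(cfg$seed, 101L))
  fs <- generate_fragments(truth$structure, cfg$tree_depth)
  masses <- vapply(fs$fragments, `[[`, numeric(1), "mass")
  matchable <- vapply(fs$fragments, `[[`, logical(1), "matchable")
  pool <- sort(unique(round(masses[matchable], 6)))
  n_sig <- min(cfg$n_signal_peaks, length(pool))
  if (n_sig < cfg$n_signal_peaks) {
    message("only ", n_sig, " distinct fragment masses available for '",
            truth$id, "'")
  }
  sig_mass <- sort(sample(pool, n_sig))
  sig_mz <- theoretical_ion_mz(sig_mass, type, 0L) +
    rnorm(n_sig, 0, cfg$mz_jitter_sd)
  sig_int <- runif(n_sig, cfg$intensity_range[1], cfg$intensity_range[2])
  mz <- sig_mz
  int <- sig_int
  if (cfg$n_noise_peaks > 0L) {
    prec_mz <- theoretical_ion_mz(truth$mass, type, 0L)
    shifts <- c(-1L, 0L, 1L)
    forbidden <- as.vector(outer(theoretical_ion_mz(pool, type, 0L),
                                 shifts * .ISOTOPE_MASS[["H"]], `+`))
    noise <- numeric(0)
    tries <- 0L
    while (length(noise) < cfg$n_noise_peaks && tries < 1000L) {
      m <- runif(1, 50, max(51, prec_mz - 1))
      tries <- tries + 1L
      if (all(abs(forbidden - m) > 0.02)) noise <- c(noise, m)
    }
    mz <- c(mz, noise)
    int <- c(int, runif(length(noise), cfg$intensity_range[1],
                        cfg$intensity_range[2]))
  }
  spec <- ms2_spectrum(mz, int, neutral_mass = truth$mass, type = type)
  attr(spec, "ground_truth") <- data.frame(mass = sig_mass, mz = sig_mz)
  spec
}

# One structural perturbation: either a formula-preserving double-edge swap
# (two bonds of equal order exchange endpoints) or an element-label swap
# between two atoms. The caller validates formula preservation and
# connectivity.
.perturb_structure <- function(s) {
  n <- n_atoms(s)
  nb <- n_bonds(s)
  op <- if (nb >= 2L && runif(1) < 0.7) "swap_edges" else "swap_labels"
  if (op == "swap_edges") {
    ks <- sample(nb, 2L)
    o1 <- s$bond_orders[ks[1]]; o2 <- s$bond_orders[ks[2]]
    if (o1 != o2) return(NULL)
    a <- s$bonds[ks[1], 1]; b <- s$bonds[ks[1], 2]
    cc <- s$bonds[ks[2], 1]; d <- s$bonds[ks[2], 2]
    if (length(unique(c(a, b, cc, d))) < 4L) return(NULL)
    # two rewirings preserve all degrees; pick one at random
    new_pairs <- if (runif(1) < 0.5) rbind(c(a, cc), c(b, d))
                 else rbind(c(a, d), c(b, cc))
    bonds <- s$bonds
    bonds[ks[1], ] <- new_pairs[1, ]
    bonds[ks[2], ] <- new_pairs[2, ]
    key <- paste(pmin(bonds[, 1], bonds[, 2]),
                 pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) return(NULL)
    tryCatch(.new_structure("", s$elements, s$charges, bonds[, 1],
                            bonds[, 2], s$bond_orders),
             error = function(e) NULL)
  } else {
    idx <- sample(n, 2L)
    if (s$elements[idx[1]] == s$elements[idx[2]]) return(NULL)
    els <- s$elements
    els[idx] <- els[rev(idx)]
    tryCatch(.new_structure("", els, s$charges, s$bonds[, 1], s$bonds[, 2],
                            s$bond_orders),
             error = function(e) NULL)
  }
}

#' Generate formula-preserving decoy candidates
#'
#' Decoys emulate an exact-mass database retrieval without any database:
#' random bond-rewiring and element-label swaps constrained to preserve the
#' molecular formula (hence the exact mass), rejecting disconnected results
#' and skeletons already seen (by InChIKey first block, including the
#' truth's).
#'
#' @param truth A candidate record.
#' @param n_decoys Number of decoys requested.
#' @param seed Integer seed.
#' @param max_tries Attempt budget before giving up (decoys found so far
#'   are returned with a message).
#' @return A `candidate_set` of decoys with identifiers `<id>_D<k>`.
#' @export
make_decoys <- function(truth, n_decoys = 10L, seed = 1L,
                        max_tries = 2000L) {
  set.seed(.derive_seed(seed, 202L))
  target <- format(truth$formula)
  seen <- inchikey_first_block(truth$structure)
  decoys <- list()
  tries <- 0L
  while (length(decoys) < n_decoys && tries < max_tries) {
    tries <- tries + 1L
    # several accepted perturbation steps per decoy: database isomers at the
    # same exact mass are structurally diverse, not one bond swap away
    n_steps <- sample(3:8, 1L)
    cand <- truth$structure
    for (step in seq_len(n_steps)) {
      nxt <- NULL
      for (attempt in 1:25) {
        prop <- .perturb_structure(cand)
        if (!is.null(prop) && is_connected(prop) &&
            format(molecular_formula(prop)) == target) {
          nxt <- prop
          break
        }
      }
      if (is.null(nxt)) break
      cand <- nxt
    }
    if (identical(cand, truth$structure)) next
    smi <- tryCatch(structure_smiles(cand), error = function(e) NULL)
    if (is.null(smi)) next
    cand$source_text <- smi
    fb <- tryCatch(inchikey_first_block(cand), error = function(e) NULL)
    if (is.null(fb) || fb %in% seen) next
    seen <- c(seen, fb)
    k <- length(decoys) + 1L
    decoys[[k]] <- list(id = paste0(truth$id, "_D", k), structure = cand,
                        properties = list(InChIKeyBlock1 = fb))
  }
  if (length(decoys) < n_decoys) {
    message("generated ", length(decoys), " of ", n_decoys,
            " requested decoys for '", truth$id, "'")
  }
  candidate_set(decoys)
}

#' Simulate a retention-time training set
#'
#' Samples structures from a library, computes their logP with the internal
#' descriptor and derives retention times by inverting the true line
#' `logP = a*RT + b`. Gaussian noise (logP units) is applied to the reported
#' logP values, emulating logP prediction error -- the dominant error source
#' in retention calibration -- so the fitted slope is an unbiased estimate
#' of `true_a`.
#'
#' @param library A `candidate_set` to sample structures from.
#' @param true_a,true_b True line coefficients.
#' @param noise_sd Gaussian noise in logP units (0 gives an exact line).
#' @param n Number of training pairs.
#' @param seed Integer seed.
#' @return Data frame with columns `rt` and `logp`.
#' @export
simulate_rt_training <- function(library, true_a = 0.35, true_b = -1,
                                 noise_sd = 0.3, n = 50L, seed = 1L) {
  stopifnot(n >= 2L, true_a != 0)
  set.seed(.derive_seed(seed, 303L))
  idx <- sample(length(library), n, replace = TRUE)
  smiles <- vapply(idx, function(i) {
    structure_smiles(library[[i]]$structure)
  }, character(1))
  logp_true <- compute_logp(smiles)
  rt <- (logp_true - true_b) / true_a
  logp <- logp_true + rnorm(n, 0, noise_sd)
  inchi <- vapply(idx, function(i) {
    structure_inchi(library[[i]]$structure)
  }, character(1))
  data.frame(rt = rt, logp = logp, inchi = inchi,
             stringsAsFactors = FALSE)
}

#' Build a complete synthetic identification case
#'
#' Truth plus formula-preserving decoys, a simulated spectrum of the truth,
#' and synthetic reference counts in which the truth's count is boosted
#' relative to the decoys' Poisson counts.
#'
#' @param truth A candidate record (e.g. from [make_toy_library()]).
#' @param n_decoys Number of decoys.
#' @param cfg A `simulation_config`.
#' @param type Precursor ion type name.
#' @return List with `spectrum` (an `ms2_spectrum`), `candidates` (a
#'   `candidate_set` with the truth shuffled among the decoys, each record
#'   carrying a `ReferenceCount` property) and `truth_id`.
#' @export
make_identification_case <- function(truth, n_decoys = 10L,
                                     cfg = simulation_config(),
                                     type = "[M+H]+") {
  decoys <- make_decoys(truth, n_decoys, seed = cfg$seed)
  spec <- simulate_spectrum(truth, cfg, type = type)
  set.seed(.derive_seed(cfg$seed, 404L))
  recs <- c(list(truth), unclass(decoys))
  ref_mean <- 20
  counts <- stats::rpois(length(recs), ref_mean)
  counts[1] <- round(cfg$ref_boost * ref_mean)
  for (i in seq_along(recs)) {
    recs[[i]]$properties$ReferenceCount <- counts[i]
  }
  recs <- recs[sample(length(recs))]
  list(spectrum = spec, candidates = candidate_set(recs),
       truth_id = truth$id)
}

#' Write a synthetic case in the pipeline's external formats
#'
#' Emits the peak list, candidate CSV (with `ReferenceCount` property), a
#' suspect list holding the truth's InChIKey and a retention-time training
#' file, so fixture-driven tests exercise the real readers.
#'
#' @param case Result of [make_identification_case()].
#' @param dir Output directory (created if needed).
#' @param rt_training Optional data frame from [simulate_rt_training()].
#' @return Named list of the written paths.
#' @export
write_fixture_files <- function(case, dir, rt_training = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$peaklist <- file.path(dir, "peaklist.txt")
  writeLines(sprintf("%.6f %.2f", case$spectrum$peaks$mz,
                     case$spectrum$peaks$intensity), paths$peaklist)
  paths$candidates <- file.path(dir, "candidates.csv")
  # SMILES round-trips the stored graph verbatim; InChI normalisation can
  # move protons on unusual decoy valences
  df <- do.call(rbind, lapply(unclass(case$candidates), function(r) {
    data.frame(Identifier = r$id,
               SMILES = structure_smiles(r$structure),
               ReferenceCount = r$properties$ReferenceCount %||% 0,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, paths$candidates, row.names = FALSE)
  truth <- case$candidates[[match(case$truth_id,
                                  candidate_ids(case$candidates))]]
  paths$suspects <- file.path(dir, "suspects.txt")
  writeLines(inchikey(truth$structure), paths$suspects)
  if (!is.null(rt_training)) {
    paths$rt_training <- file.path(dir, "rt_training.csv")
    out <- data.frame(RetentionTime = rt_training$rt,
                      UserLogP = rt_training$logp)
    if (!is.null(rt_training$inchi)) out$InChI <- rt_training$inchi
    utils::write.csv(out, paths$rt_training, row.names = FALSE)
  }
  paths
}
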