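# End-to-end orchestration: load -> select -> filter -> fragment -> match ->
# score -> normalize -> combine -> dedupe -> rank -> write.

.BUILTIN_TERMS <- c("FragmenterScore", "RetentionTimeScore",
                    "ReferenceScore", "SmartsInclusionScore",
                    "SmartsExclusionScore", "SuspectListScore")

#' Run the identification pipeline
#'
#' Executes the stages in a fixed order: read candidates, select by
#' mass/formula/identifiers, unconnected filter, element filter,
#' substructure filter, suspect-inclusion filter, fragmentation and peak
#' matching (fragmenter score), auxiliary scores (reference, retention
#' time, substructure, suspect, user columns), per-term normalization,
#' weighted combination, InChIKey first-block deduplication, ranking and
#' (optionally) writing. Deterministic for fixed inputs.
#'
#' @param params A `parameter_set` (see [parameter_set()] /
#'   [read_parameters()]).
#' @param spectrum Optionally, an `ms2_spectrum` to use instead of reading
#'   `PeakListPath` (the precursor specification still comes from
#'   `params`).
#' @param candidates Optionally, a `candidate_set` to use instead of
#'   reading `LocalDatabasePath`.
#' @return An object of class `fragrank_result`: list with `results` (the
#'   ranked table of [results_table()]), `candidates` (the scored, deduped
#'   `candidate_set`) and `report` (per-stage counts and warnings).
#' @export
run_pipeline <- function(params, spectrum = NULL, candidates = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  report <- list(counts = list(), warnings = character(0),
                 parameters = unclass(params))
  note <- function(stage, candidates) {
    report$counts[[stage]] <<- length(candidates)
  }
  warn <- function(...) {
    msg <- paste0(...)
    report$warnings <<- c(report$warnings, msg)
    warning(msg, call. = FALSE)
  }

  if (params$DatabaseType %in% .ONLINE_DB_TYPES && is.null(candidates)) {
    stop("database type '", params$DatabaseType,
         "' requires network retrieval, which is not bundled; ",
         "use LocalCSV/LocalSDF")
  }

  # precursor specification
  prec_mass <- params$NeutralPrecursorMass
  prec_formula <- params$NeutralPrecursorMolecularFormula
  prec_ids <- params$PrecursorIdentifiers
  if (!is.null(prec_formula)) {
    prec_mass <- monoisotopic_mass(parse_formula(prec_formula))
  }

  if (is.null(candidates)) {
    candidates <- read_candidates(params$LocalDatabasePath,
                                  format = sub("^Local", "",
                                               params$DatabaseType))
  }
  note("loaded", candidates)

  candidates <- if (!is.null(prec_ids)) {
    select_candidates(candidates, ids = prec_ids)
  } else if (!is.null(prec_formula)) {
    select_candidates(candidates, formula = prec_formula)
  } else {
    select_candidates(candidates, mass = prec_mass,
                      ppm = params$DatabaseSearchRelativeMassDeviation)
  }
  note("selected", candidates)

  if (isTRUE(params$FilterUnconnected)) {
    candidates <- filter_unconnected(candidates)
  }
  note("after_unconnected_filter", candidates)

  if (!is.null(params$FilterElementsOnly) ||
      !is.null(params$FilterElementsMust) ||
      !is.null(params$FilterElementsExclude)) {
    candidates <- filter_elements(candidates,
                                  only = params$FilterElementsOnly,
                                  must = params$FilterElementsMust,
                                  exclude = params$FilterElementsExclude)
  }
  note("after_element_filter", candidates)

  candidates <- filter_substructures(
    candidates,
    include = params$FilterSmartsInclusion %||% character(0),
    exclude = params$FilterSmartsExclusion %||% character(0))
  note("after_substructure_filter", candidates)

  suspects <- if (!is.null(params$SuspectListPath)) {
    read_suspect_list(params$SuspectListPath)
  }
  if (isTRUE(params$SuspectFilter)) {
    if (is.null(suspects)) stop("SuspectFilter=TRUE needs SuspectListPath")
    candidates <- suspect_inclusion_filter(candidates, suspects)
  }
  note("after_suspect_filter", candidates)

  if (!length(candidates)) {
    warn("no candidates left after filtering; empty result")
    empty <- data.frame()
    return(structure(list(results = empty, candidates = candidates,
                          report = report), class = "fragrank_result"))
  }

  # spectrum
  if (is.null(spectrum)) {
    if (is.null(prec_mass)) {
      # identifier-based query: anchor the relative-mass scale on the
      # selected candidates themselves
      prec_mass <- stats::median(vapply(candidates, `[[`, numeric(1),
                                        "mass"))
    }
    spectrum <- read_peaklist(params$PeakListPath,
                              neutral_mass = prec_mass,
                              type = params$PrecursorIonType,
                              retention_time =
                                params$ExperimentalRetentionTime)
  }

  w <- weight_config(setNames(params$ScoreWeights, params$ScoreTerms))
  settings <- match_settings(
    relative_ppm = params$FragmentPeakMatchRelativeMassDeviation,
    absolute_da = params$FragmentPeakMatchAbsoluteMassDeviation,
    hydrogen_shifts = params$HydrogenShifts)

  terms_requested <- params$ScoreTerms
  raw <- matrix(0, length(candidates), length(terms_requested),
                dimnames = list(candidate_ids(candidates), terms_requested))

  # fragmentation + matching
  if ("FragmenterScore" %in% terms_requested) {
    bde <- default_bde_table()
    for (i in seq_along(candidates)) {
      r <- candidates[[i]]
      fs <- generate_fragments(r$structure, params$MaximumTreeDepth, bde)
      asg <- match_peaks(spectrum, fs, settings)
      raw[i, "FragmenterScore"] <- fragmenter_score(asg, spectrum, w)
      candidates[[i]]$properties$NoExplPeaks <- nrow(asg)
      candidates[[i]]$properties$NumberPeaksUsed <- nrow(spectrum$peaks)
    }
  }

  props_df <- function(cols) {
    out <- data.frame(row.names = seq_along(candidates))
    for (cn in cols) out[[cn]] <- .candidate_property(candidates, cn)
    out
  }

  if ("ReferenceScore" %in% terms_requested) {
    sources <- params$ReferenceSources %||% "ReferenceCount"
    ref <- combined_reference_score(props_df(sources), sources)
    raw[, "ReferenceScore"] <- ref$raw
  }

  if ("RetentionTimeScore" %in% terms_requested) {
    if (is.null(params$RetentionTimeTrainingPath) ||
        is.null(params$ExperimentalRetentionTime)) {
      stop("RetentionTimeScore needs RetentionTimeTrainingPath and ",
           "ExperimentalRetentionTime")
    }
    training <- read_rt_training(params$RetentionTimeTrainingPath,
                                 logp_column = params$LogPColumn)
    model <- fit_rt_model(training$rt, training$logp,
                          sigma = params$RTSigma,
                          logp_source = attr(training, "logp_source"))
    cand_logp <- if (!is.null(params$LogPColumn)) {
      suppressWarnings(as.numeric(
        .candidate_property(candidates, params$LogPColumn)))
    } else {
      compute_logp(vapply(candidates, function(r) {
        structure_smiles(r$structure)
      }, character(1)))
    }
    raw[, "RetentionTimeScore"] <-
      rt_score(model, params$ExperimentalRetentionTime, cand_logp)
  }

  smiles_all <- NULL
  get_smiles <- function() {
    if (is.null(smiles_all)) {
      smiles_all <<- vapply(candidates, function(r) {
        structure_smiles(r$structure)
      }, character(1))
    }
    smiles_all
  }

  if ("SmartsInclusionScore" %in% terms_requested) {
    pats <- params$ScoreSmartsInclusion %||% character(0)
    counts <- substructure_match_count(get_smiles(), pats)
    raw[, "SmartsInclusionScore"] <- as.numeric(counts)
  }
  if ("SmartsExclusionScore" %in% terms_requested) {
    pats <- params$ScoreSmartsExclusion %||% character(0)
    counts <- substructure_match_count(get_smiles(), pats)
    raw[, "SmartsExclusionScore"] <- as.numeric(length(pats) - counts)
  }
  if ("SuspectListScore" %in% terms_requested) {
    if (is.null(suspects)) stop("SuspectListScore needs SuspectListPath")
    raw[, "SuspectListScore"] <-
      suspect_score(candidate_first_blocks(candidates), suspects)
  }

  user_terms <- setdiff(terms_requested, .BUILTIN_TERMS)
  for (nm in user_terms) {
    v <- suppressWarnings(as.numeric(.candidate_property(candidates, nm)))
    if (all(is.na(v))) {
      stop("score term '", nm, "' is neither built in nor a numeric ",
           "candidate property")
    }
    v[is.na(v)] <- 0
    raw[, nm] <- v
  }

  norm <- apply(raw, 2, normalize_terms)
  if (is.null(dim(norm))) {
    norm <- matrix(norm, nrow = nrow(raw), dimnames = dimnames(raw))
  }
  final <- combine_final(norm, w)

  for (i in seq_along(candidates)) {
    candidates[[i]]$score_terms_raw <-
      setNames(as.list(as.numeric(raw[i, ])), colnames(raw))
    candidates[[i]]$score_terms <-
      setNames(as.list(as.numeric(norm[i, ])), colnames(norm))
    candidates[[i]]$final_score <- final[i]
  }
  note("scored", candidates)

  candidates <- dedupe_first_block(candidates)
  note("after_dedupe", candidates)

  results <- results_table(candidates)
  if (!is.null(params$ResultsPath)) {
    write_results(results, params$ResultsPath,
                  format = params$ResultsFormat)
  }
  structure(list(results = results, candidates = candidates,
                 report = report),
            class = "fragrank_result")
}

#' @export
print.fragrank_result <- function(x, ...) {
  cat("<fragrank_result> ", nrow(x$results), " ranked candidates\n",
      sep = "")
  if (nrow(x$results)) {
    cols <- intersect(c("Rank", "Identifier", "MolecularFormula", "Score"),
                      names(x$results))
    print(head(x$results[, cols], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.fragrank_result <- function(object, ...) {
  cat("Pipeline stage counts:\n")
  for (nm in names(object$report$counts)) {
    cat(sprintf("  %-28s %d\n", nm, object$report$counts[[nm]]))
  }
  if (length(object$report$warnings)) {
    cat("Warnings:\n")
    for (wmsg in object$report$warnings) cat("  -", wmsg, "\n")
  }
  invisible(object)
}

#' Re-score previously exported results
#'
#' Implements the two-step user-score workflow: a results table exported by
#' [run_pipeline()] (or [write_results()]) is augmented externally with new
#' columns (e.g. externally predicted logP or another fragmenter's
#' probabilities) and re-imported here for a new weighted combination
#' without re-fragmenting. Each requested term is taken from the column of
#' the same name (a `<term>_Raw` column is preferred when present),
#' normalized to the list maximum and combined with the given weights.
#'
#' @param results Data frame, or path to a delimited results file
#'   (pipe-separated by default; comma and tab are auto-detected).
#' @param score_terms Character vector of term/column names to combine.
#' @param weights Numeric weights matching `score_terms`.
#' @param rt_unknown,logp_column,rt_model Optionally recompute a
#'   `RetentionTimeScore` term from a candidate logP column: supply the
#'   unknown's retention time, the column name and a fitted [fit_rt_model()]
#'   model (tagged with the same logP source).
#' @return A new results data frame sorted by the recombined score, with
#'   updated `Score` and `Rank` columns.
#' @export
rescore_results <- function(results, score_terms, weights,
                            rt_unknown = NULL, logp_column = NULL,
                            rt_model = NULL) {
  if (is.character(results)) {
    first <- readLines(results, n = 1L)
    sep <- if (grepl("|", first, fixed = TRUE)) "|"
           else if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    results <- utils::read.table(results, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE)
  }
  stopifnot(length(score_terms) == length(weights))
  if (!is.null(rt_model)) {
    if (is.null(rt_unknown) || is.null(logp_column)) {
      stop("recomputing the retention term needs rt_unknown and logp_column")
    }
    if (!identical(rt_model$logp_source, logp_column)) {
      stop("rt_model was fitted on logP source '", rt_model$logp_source,
           "' but candidates use '", logp_column,
           "'; model and candidates must share the source")
    }
    cand_logp <- suppressWarnings(as.numeric(results[[logp_column]]))
    results$RetentionTimeScore_Raw <-
      rt_score(rt_model, rt_unknown, cand_logp)
  }
  src <- vapply(score_terms, function(nm) {
    rawcol <- paste0(nm, "_Raw")
    if (rawcol %in% names(results)) rawcol else nm
  }, character(1))
  norm <- attach_user_scores(results, unname(src))
  colnames(norm) <- score_terms
  w <- weight_config(setNames(weights, score_terms))
  results$Score <- combine_final(norm, w)
  for (i in seq_along(score_terms)) {
    results[[score_terms[i]]] <- norm[, score_terms[i]]
  }
  results <- results[order(-results$Score, results$Identifier), ]
  results$Rank <- vapply(results$Score, function(s) {
    1L + sum(results$Score > s)
  }, integer(1))
  rownames(results) <- NULL
  results
}

#' Write a results table in pipe-separated format
#'
#' The exchange format of the two-step user-score workflow.
#'
#' @param results Results data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipe_results <- function(results, path) {
  utils::write.table(results, path, sep = "|", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
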