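# Candidate records, database readers/writers and parameter files.

#' Build a candidate set
#'
#' @param records List of candidate records; each a list with at least `id`
#'   and `structure` (a `structure_graph`). `formula` and `mass` are filled
#'   in from the structure when absent; extra named entries go into
#'   `properties`.
#' @return An object of class `candidate_set` (a list of records).
#' @export
candidate_set <- function(records) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate candidate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- lapply(records, function(r) {
    stopifnot(inherits(r$structure, "structure_graph"))
    if (is.null(r$formula)) r$formula <- molecular_formula(r$structure)
    if (is.null(r$mass)) r$mass <- monoisotopic_mass(r$formula)
    if (is.null(r$properties)) r$properties <- list()
    r
  })
  structure(records, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", length(x), " candidates\n", sep = "")
  if (length(x)) {
    for (r in head(x, 5L)) {
      cat("  ", r$id, "  ", format(r$formula), "  ",
          sprintf("%.4f", r$mass), "\n", sep = "")
    }
    if (length(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
`[.candidate_set` <- function(x, i) {
  structure(unclass(x)[i], class = "candidate_set")
}

#' Candidate identifiers
#' @param candidates A `candidate_set`.
#' @return Character vector of identifiers.
#' @export
candidate_ids <- function(candidates) {
  vapply(candidates, `[[`, character(1), "id")
}

# Property lookup across a candidate set; missing -> NA.
.candidate_property <- function(candidates, name) {
  vapply(candidates, function(r) {
    v <- r$properties[[name]]
    if (is.null(v) || !nzchar(as.character(v))) NA_character_
    else as.character(v)
  }, character(1))
}

#' Read a local candidate database
#'
#' CSV databases have a header line with an `Identifier` column and an
#' `InChI` and/or `SMILES` column (InChI preferred when both are present);
#' all other columns are kept as properties (e.g. reference counts,
#' `UserLogP`). SDF databases carry properties as SD data fields with the
#' identifier in the `Identifier` field or the record title. Records whose
#' structure fails to parse, or that carry a net formal charge, are skipped
#' with a warning. A `MonoisotopicMass` property disagreeing with the
#' computed mass by more than 1e-3 Da logs a warning; the computed value
#' wins.
#'
#' @param path Path to the database file.
#' @param format `"CSV"` or `"SDF"`; default guesses from the extension.
#' @return A `candidate_set`.
#' @export
read_candidates <- function(path, format = NULL) {
  if (!file.exists(path)) stop("candidate database not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "SDF" else "CSV"
  }
  format <- toupper(format)
  records <- switch(format,
    CSV = .read_candidates_csv(path),
    SDF = .read_candidates_sdf(path),
    stop("unsupported candidate database format: ", format)
  )
  if (!length(records)) stop("no valid candidate records in ", path)
  candidate_set(records)
}

.finish_record <- function(id, structure, properties) {
  if (net_charge(structure) != 0L) {
    warning("candidate '", id, "' carries a net formal charge; skipped")
    return(NULL)
  }
  rec <- list(id = id, structure = structure, properties = properties)
  rec$formula <- molecular_formula(structure)
  rec$mass <- monoisotopic_mass(rec$formula)
  stated <- suppressWarnings(as.numeric(properties[["MonoisotopicMass"]]))
  if (length(stated) == 1L && !is.na(stated) &&
      abs(stated - rec$mass) > 1e-3) {
    warning("candidate '", id, "': stated monoisotopic mass ", stated,
            " disagrees with computed ", round(rec$mass, 5),
            "; using the computed value")
  }
  rec
}

.read_candidates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"Identifier" %in% names(df)) {
    stop("candidate CSV lacks an 'Identifier' column: ", path)
  }
  struct_col <- if ("InChI" %in% names(df)) "InChI"
                else if ("SMILES" %in% names(df)) "SMILES"
                else stop("candidate CSV needs an 'InChI' or 'SMILES' column")
  prop_cols <- setdiff(names(df), "Identifier")
  records <- list()
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$Identifier[i])
    s <- tryCatch(parse_structure(df[[struct_col]][i], id = id),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("skipping candidate '", id, "': unparsable structure")
      skipped <- skipped + 1L
      next
    }
    props <- as.list(df[i, prop_cols, drop = FALSE])
    rec <- .finish_record(id, s, props)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  attr(records, "skipped") <- skipped
  records
}

.read_candidates_sdf <- function(path) {
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(path))
  records <- list()
  for (i in seq_along(ChemmineR::cid(sdfset))) {
    sdf <- sdfset[[i]]
    props <- as.list(ChemmineR::datablock(sdf))
    molblock <- paste(ChemmineR::sdf2str(sdf), collapse = "\n")
    title <- ChemmineR::sdfid(sdfset[i])
    id <- as.character(props[["Identifier"]] %||% title %||% paste0("SDF", i))
    s <- tryCatch(.parse_molblock(molblock), error = function(e) NULL)
    if (is.null(s) || n_atoms(s) == 0L) {
      warning("skipping candidate '", id, "': unparsable SDF record")
      next
    }
    s$source_text <- tryCatch(structure_smiles(s), error = function(e) "")
    rec <- .finish_record(id, s, props)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records
}

#' Select candidates by precursor mass, formula or identifier
#'
#' Mass mode keeps candidates whose neutral monoisotopic mass lies within
#' `target * ppm * 1e-6` of the target (symmetric, inclusive). Formula mode
#' keeps exact formula matches; identifier mode keeps the listed
#' identifiers.
#'
#' @param candidates A `candidate_set`.
#' @param mass Neutral monoisotopic target mass in Da.
#' @param ppm Relative window half-width in ppm (default 5).
#' @param formula Molecular formula (string or `chem_formula`).
#' @param ids Character vector of identifiers.
#' @return The filtered `candidate_set`.
#' @export
select_candidates <- function(candidates, mass = NULL, ppm = 5,
                              formula = NULL, ids = NULL) {
  modes <- c(!is.null(mass), !is.null(formula), !is.null(ids))
  if (sum(modes) != 1L) {
    stop("give exactly one of mass, formula or ids")
  }
  keep <- if (!is.null(mass)) {
    vapply(candidates, function(r) {
      abs(r$mass - mass) <= mass * ppm * 1e-6
    }, logical(1))
  } else if (!is.null(formula)) {
    if (is.character(formula)) formula <- parse_formula(formula)
    target <- format(formula)
    vapply(candidates, function(r) format(r$formula) == target, logical(1))
  } else {
    candidate_ids(candidates) %in% ids
  }
  if (!any(keep)) message("candidate selection is empty")
  candidates[keep]
}

#' Results table of a scored candidate set
#'
#' @param candidates A scored `candidate_set` (as returned inside
#'   [run_pipeline()] results).
#' @return Data frame with identifier, structure encodings, formula, mass,
#'   every raw and normalized score term, the final score and the rank
#'   (1 + number of strictly greater final scores).
#' @export
results_table <- function(candidates) {
  rows <- lapply(candidates, function(r) {
    base <- data.frame(
      Identifier = r$id,
      InChI = tryCatch(structure_inchi(r$structure),
                       error = function(e) NA_character_),
      SMILES = tryCatch(structure_smiles(r$structure),
                        error = function(e) NA_character_),
      MolecularFormula = format(r$formula),
      MonoisotopicMass = r$mass,
      stringsAsFactors = FALSE
    )
    for (nm in names(r$score_terms_raw)) {
      base[[paste0(nm, "_Raw")]] <- r$score_terms_raw[[nm]]
    }
    for (nm in names(r$score_terms)) base[[nm]] <- r$score_terms[[nm]]
    base$Score <- r$final_score
    base
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$Score, df$Identifier), ]
  df$Rank <- vapply(df$Score, function(s) 1L + sum(df$Score > s), integer(1))
  rownames(df) <- NULL
  df
}

#' Write ranked results
#'
#' CSV output carries the full results table sorted by descending final
#' score; SDF output carries the same values as SD property fields together
#' with the connection table.
#'
#' @param results Data frame from [results_table()] (or a scored
#'   `candidate_set`).
#' @param path Output file path.
#' @param format `"CSV"` or `"SDF"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("CSV", "SDF")) {
  format <- match.arg(format)
  if (inherits(results, "candidate_set")) results <- results_table(results)
  if (format == "CSV") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(results))) {
      mol <- suppressWarnings(
        ChemmineOB::convertFormat("SMI", "SDF",
                                  paste0(results$SMILES[i], "\t",
                                         results$Identifier[i])))
      mol <- sub("\\$\\$\\$\\$\n?$", "", mol)
      writeLines(sub("\n$", "", mol), con)
      for (nm in setdiff(names(results), "SMILES")) {
        writeLines(c(paste0("> <", nm, ">"),
                     as.character(results[[nm]][i]), ""), con)
      }
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

# ---- parameter files --------------------------------------------------------

.PARAM_DEFAULTS <- list(
  DatabaseType = "LocalCSV",
  PrecursorIonType = "[M+H]+",
  MaximumTreeDepth = 2L,
  FragmentPeakMatchRelativeMassDeviation = 5,
  FragmentPeakMatchAbsoluteMassDeviation = 0.001,
  DatabaseSearchRelativeMassDeviation = 5,
  HydrogenShifts = c(-1L, 0L, 1L),
  ScoreTerms = "FragmenterScore",
  ScoreWeights = 1,
  FilterUnconnected = TRUE,
  SuspectFilter = FALSE,
  RTSigma = 1.5,
  ResultsFormat = "CSV",
  RandomSeed = 1L
)

.ONLINE_DB_TYPES <- c("PubChem", "ChemSpider", "KEGG")

#' Build a parameter set
#'
#' @param ... Named parameters; see Details for the recognised keys.
#' @details Mandatory keys: `PeakListPath`, `LocalDatabasePath` and exactly
#'   one precursor specification among `NeutralPrecursorMass`,
#'   `NeutralPrecursorMolecularFormula` and `PrecursorIdentifiers`.
#'   Optional keys with defaults: `DatabaseType` (`LocalCSV`/`LocalSDF`;
#'   the online types are accepted but resolve to a stub), `PrecursorIonType`
#'   (`[M+H]+`), `MaximumTreeDepth` (2),
#'   `FragmentPeakMatchRelativeMassDeviation` (5 ppm),
#'   `FragmentPeakMatchAbsoluteMassDeviation` (0.001 Da),
#'   `DatabaseSearchRelativeMassDeviation` (5 ppm), `HydrogenShifts`
#'   (-1,0,1), `ScoreTerms`/`ScoreWeights` (FragmenterScore/1),
#'   `FilterUnconnected` (TRUE), `FilterElementsOnly`/`FilterElementsMust`/
#'   `FilterElementsExclude`, `FilterSmartsInclusion`/`FilterSmartsExclusion`
#'   (candidate filters), `ScoreSmartsInclusion`/`ScoreSmartsExclusion`
#'   (scored SMARTS lists), `ReferenceSources` (property columns summed into
#'   the combined reference term), `SuspectListPath`, `SuspectFilter`
#'   (FALSE), `RetentionTimeTrainingPath`, `ExperimentalRetentionTime`,
#'   `LogPColumn` (candidate logP property; absent means the internal
#'   descriptor), `RTSigma` (1.5), `UserScoreColumns`, `ResultsPath`,
#'   `ResultsFormat` (CSV), `RandomSeed` (1).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(...) {
  params <- list(...)
  known <- c(names(.PARAM_DEFAULTS), "PeakListPath", "LocalDatabasePath",
             "NeutralPrecursorMass", "NeutralPrecursorMolecularFormula",
             "PrecursorIdentifiers", "FilterElementsOnly",
             "FilterElementsMust", "FilterElementsExclude",
             "FilterSmartsInclusion", "FilterSmartsExclusion",
             "ScoreSmartsInclusion", "ScoreSmartsExclusion",
             "ReferenceSources", "SuspectListPath", "SuspectFilter",
             "RetentionTimeTrainingPath", "ExperimentalRetentionTime",
             "LogPColumn", "UserScoreColumns", "ResultsPath")
  unknown <- setdiff(names(params), known)
  if (length(unknown)) {
    warning("ignoring unknown parameter key(s): ",
            paste(unknown, collapse = ", "))
    params <- params[setdiff(names(params), unknown)]
  }
  for (nm in names(.PARAM_DEFAULTS)) {
    if (is.null(params[[nm]])) params[[nm]] <- .PARAM_DEFAULTS[[nm]]
  }
  missing_keys <- setdiff(c("PeakListPath", "LocalDatabasePath"),
                          names(params))
  if (params$DatabaseType %in% .ONLINE_DB_TYPES) {
    missing_keys <- setdiff(missing_keys, "LocalDatabasePath")
  }
  prec_keys <- intersect(c("NeutralPrecursorMass",
                           "NeutralPrecursorMolecularFormula",
                           "PrecursorIdentifiers"), names(params))
  if (length(prec_keys) == 0L) {
    missing_keys <- c(missing_keys, "a precursor specification")
  }
  if (length(missing_keys)) {
    stop("missing mandatory parameter(s): ",
         paste(missing_keys, collapse = ", "))
  }
  if (length(prec_keys) > 1L) {
    stop("conflicting precursor specifications: ",
         paste(prec_keys, collapse = ", "))
  }
  if (length(params$ScoreWeights) != length(params$ScoreTerms)) {
    stop("ScoreTerms and ScoreWeights differ in length")
  }
  if (any(params$ScoreWeights < 0)) stop("negative score weight")
  precursor_type(params$PrecursorIonType)  # validates the name
  structure(params, class = "parameter_set")
}

#' Read a key=value parameter file
#'
#' One `Key = value` pair per line; `#` comments and blank lines are
#' ignored. List-valued keys (`ScoreTerms`, `ScoreWeights`,
#' `HydrogenShifts`, element and SMARTS filters, `ReferenceSources`,
#' `UserScoreColumns`, `PrecursorIdentifiers`) take comma-separated values.
#' Unknown keys warn; missing mandatory keys error.
#'
#' @param path Path to the parameter file.
#' @param overrides Named list of values taking precedence over the file.
#' @return A `parameter_set`.
#' @export
read_parameters <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  params <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed parameter line (expected key=value): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    params[[key]] <- val
  }
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  list_keys <- c("ScoreTerms", "ScoreWeights", "HydrogenShifts",
                 "FilterElementsOnly", "FilterElementsMust",
                 "FilterElementsExclude", "FilterSmartsInclusion",
                 "FilterSmartsExclusion", "ScoreSmartsInclusion",
                 "ScoreSmartsExclusion", "ReferenceSources",
                 "UserScoreColumns", "PrecursorIdentifiers")
  num_keys <- c("NeutralPrecursorMass", "MaximumTreeDepth",
                "FragmentPeakMatchRelativeMassDeviation",
                "FragmentPeakMatchAbsoluteMassDeviation",
                "DatabaseSearchRelativeMassDeviation", "ScoreWeights",
                "HydrogenShifts", "ExperimentalRetentionTime", "RTSigma",
                "RandomSeed")
  bool_keys <- c("FilterUnconnected", "SuspectFilter")
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.character(v) && nm %in% list_keys) {
      v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    }
    if (nm %in% num_keys && is.character(v)) v <- as.numeric(v)
    if (nm %in% bool_keys && is.character(v)) {
      v <- toupper(v) %in% c("TRUE", "T", "YES", "1")
    }
    params[[nm]] <- v
  }
  do.call(parameter_set, params)
}
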