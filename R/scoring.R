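# Scoring terms and their weighted combination.
#
# Every term is computed as a raw non-negative value per candidate, then
# normalized to the maximum over the candidate list, and finally combined as
# a weighted sum. Raw values are kept alongside normalized ones in the
# output.

#' Weight configuration
#'
#' Per-term weights for the final combination plus the fragmenter score
#' exponents. The default exponents follow the published optimisation on
#' merged reference spectra: alpha = 1.84 (relative mass), beta = 0.59
#' (relative intensity), gamma = 0.47 (bond dissociation energy penalty).
#'
#' @param weights Named non-negative numeric vector, term name -> weight.
#' @param alpha,beta,gamma Positive fragmenter exponents.
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(weights = c(FragmenterScore = 1),
                          alpha = 1.84, beta = 0.59, gamma = 0.47) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be a named vector")
  }
  if (any(weights < 0)) stop("negative score weight")
  if (!any(weights > 0)) stop("at least one weight must be positive")
  stopifnot(alpha > 0, beta > 0, gamma > 0)
  structure(list(weights = weights, alpha = alpha, beta = beta,
                 gamma = gamma), class = "weight_config")
}

#' Fragmenter score
#'
#' For each peak assigned a fragment, the peak's relative mass (peak m/z over
#' precursor ion m/z) raised to `alpha` times its relative intensity (over
#' the spectrum's maximum intensity) raised to `beta` is divided by the
#' fragment's cumulative bond dissociation energy raised to `gamma`, and the
#' contributions are summed. No assignments give a score of 0; the score is
#' non-negative by construction.
#'
#' @param assignments Result of [match_peaks()] for this candidate.
#' @param spec The `ms2_spectrum` that was matched.
#' @param w A `weight_config` (only the exponents are used).
#' @return Raw (unnormalized) score, >= 0.
#' @export
fragmenter_score <- function(assignments, spec, w = weight_config()) {
  if (nrow(assignments) == 0L) return(0)
  prec_mz <- theoretical_ion_mz(spec$neutral_mass, spec$precursor_type, 0L)
  rel_mass <- assignments$mz / prec_mz
  rel_int <- assignments$intensity / max(spec$peaks$intensity)
  denom <- assignments$bde
  if (any(denom <= 0)) stop("matched fragment with non-positive BDE")
  sum(rel_mass^w$alpha * rel_int^w$beta / denom^w$gamma)
}

#' Normalize raw scores to the candidate-list maximum
#'
#' Each value is divided by the maximum over the list; an all-zero list maps
#' to all zeros.
#'
#' @param values Non-negative numeric vector of raw scores.
#' @return Values scaled into `[0, 1]`.
#' @export
normalize_terms <- function(values) {
  if (!length(values)) return(values)
  if (any(values < 0)) stop("raw scores must be non-negative")
  m <- max(values)
  if (m == 0) return(values * 0)
  values / m
}

#' Weighted final score
#'
#' The final candidate score is the weighted sum of the normalized scoring
#' terms. Terms named in the weights but absent from `terms` contribute 0
#' with a warning.
#'
#' @param terms Matrix or data frame of normalized scores, one row per
#'   candidate, columns named by term.
#' @param w A `weight_config`.
#' @return Numeric vector of final scores.
#' @export
combine_final <- function(terms, w) {
  stopifnot(inherits(w, "weight_config"))
  terms <- as.matrix(terms)
  out <- numeric(nrow(terms))
  for (nm in names(w$weights)) {
    if (!nm %in% colnames(terms)) {
      warning("score term '", nm, "' missing; contributing 0")
      next
    }
    out <- out + w$weights[[nm]] * terms[, nm]
  }
  unname(out)
}

#' Count substructure matches
#'
#' Each SMARTS pattern contributes at most 1 per candidate (presence, not
#' occurrence count); overlapping patterns are counted independently.
#'
#' @param s A `structure_graph`, or character vector of SMILES.
#' @param patterns Character vector of SMARTS patterns.
#' @return Integer match count (vector if `s` is a vector of SMILES).
#' @export
#' @examples
#' \dontrun{
#' substructure_match_count(parse_structure("CCNc1nc(Cl)nc(NC(C)(C)C)n1"),
#'                          c("N[CH2][CH3]", "NC(C)(C)C"))  # 2
#' }
substructure_match_count <- function(s, patterns) {
  smiles <- if (inherits(s, "structure_graph")) structure_smiles(s) else s
  if (!length(patterns)) return(integer(length(smiles)))
  vapply(smiles, function(smi) {
    hits <- suppressWarnings(ChemmineOB::forEachMol("SMILES", smi,
      function(mol) {
        vapply(patterns, function(p) {
          n <- tryCatch(
            ChemmineOB::smartsSearch_OB(list(m = mol), p,
                                        uniqueMatches = TRUE),
            error = function(e) {
              stop("invalid SMARTS pattern '", p, "'", call. = FALSE)
            })
          as.numeric(n)
        }, numeric(1))
      }))
    sum(hits[[1]] > 0)
  }, numeric(1), USE.NAMES = FALSE) |> as.integer()
}

#' Substructure inclusion / exclusion scores
#'
#' Inclusion: match count over the list maximum. Exclusion: `n - count` over
#' the maximum of `n - count`, where `n` is the number of exclusion
#' patterns. Both are defined as 0 for every candidate when the respective
#' maximum is 0.
#'
#' @param counts Integer vector of per-candidate match counts.
#' @param n Number of patterns in the exclusion list.
#' @return Numeric score vector in `[0, 1]`.
#' @export
inclusion_score <- function(counts) normalize_terms(as.numeric(counts))

#' @rdname inclusion_score
#' @export
exclusion_score <- function(counts, n) {
  stopifnot(all(counts <= n))
  normalize_terms(as.numeric(n - counts))
}

#' Combined reference score
#'
#' Reference, data-source and patent counts from the selected sources are
#' summed per candidate (unit selector weights) and normalized to the list
#' maximum. Missing properties count as 0 (absent means unreferenced).
#'
#' @param properties Data frame of per-candidate reference counts (columns
#'   named by source, e.g. `ChemSpiderReferenceCount`).
#' @param sources Character vector naming the selected source columns.
#' @return List with `raw` (summed counts) and `score` (normalized).
#' @export
#' @examples
#' combined_reference_score(
#'   data.frame(A = c(94, 179, 32), B = c(15, 1, 0),
#'              C = c(7, 0, 0), D = c(70, 40, 21)),
#'   sources = c("A", "B", "C", "D"))$raw  # 186 220 53
combined_reference_score <- function(properties, sources) {
  if (!length(sources)) stop("empty reference source selection")
  n <- nrow(properties)
  raw <- numeric(n)
  for (src in sources) {
    v <- if (src %in% names(properties)) {
      suppressWarnings(as.numeric(properties[[src]]))
    } else {
      numeric(n)
    }
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative reference count in '", src, "'")
    raw <- raw + v
  }
  list(raw = raw, score = normalize_terms(raw))
}

#' Suspect-list score
#'
#' 1 when the candidate's InChIKey first block appears in the suspect set,
#' 0 otherwise.
#'
#' @param first_blocks Character vector of candidate InChIKey first blocks.
#' @param suspects Character vector of suspect first blocks (see
#'   [read_suspect_list()]).
#' @return Integer 0/1 vector.
#' @export
suspect_score <- function(first_blocks, suspects) {
  as.integer(first_blocks %in% suspects)
}

#' Read a suspect list
#'
#' One InChIKey per line; full 27-character keys or bare 14-character first
#' blocks are accepted. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the suspect list file.
#' @return Character vector of unique first blocks.
#' @export
read_suspect_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  blocks <- toupper(substr(lines, 1L, 14L))
  ok <- grepl("^[A-Z]{14}$", blocks)
  if (any(!ok)) {
    warning(sum(!ok), " malformed suspect-list entries skipped")
  }
  unique(blocks[ok])
}

#' Fit the retention time -> logP calibration
#'
#' Ordinary least squares fit of `logP = a * RT + b` over user-provided
#' training pairs measured on the same chromatographic system as the
#' unknown. Fewer than ten points triggers a warning (a minimum of ten data
#' points is recommended); identical retention times make the fit singular.
#'
#' @param rt Retention times in minutes.
#' @param logp logP values paired with `rt`.
#' @param sigma Standard deviation (logP units) of the Gaussian scoring
#'   kernel, default 1.5.
#' @param logp_source Tag recording where candidate logP values must come
#'   from (`"internal"` descriptor or a property column name); model and
#'   candidates must use the same source.
#' @return An object of class `rt_model` with coefficients `a` (slope) and
#'   `b` (intercept).
#' @export
fit_rt_model <- function(rt, logp, sigma = 1.5, logp_source = "internal") {
  stopifnot(length(rt) == length(logp), sigma > 0)
  ok <- is.finite(rt) & is.finite(logp)
  rt <- rt[ok]; logp <- logp[ok]
  if (length(rt) < 2L) stop("need at least two retention-time training pairs")
  if (length(unique(rt)) < 2L) {
    stop("all training retention times identical; singular fit")
  }
  if (length(rt) < 10L) {
    warning("only ", length(rt), " retention-time training pairs; ",
            "a minimum of ten data points is recommended")
  }
  fit <- stats::lm(logp ~ rt)
  structure(list(
    a = unname(stats::coef(fit)[2]),
    b = unname(stats::coef(fit)[1]),
    sigma = sigma,
    logp_source = logp_source,
    n = length(rt),
    residual_sd = suppressWarnings(summary(fit)$sigma)
  ), class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat("<rt_model> logP = ", signif(x$a, 4), " * RT + ", signif(x$b, 4),
      "  (n = ", x$n, ", sigma = ", x$sigma, ", logP source: ",
      x$logp_source, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.rt_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.rt_model <- function(object, rt, ...) object$a * rt + object$b

#' Retention time score
#'
#' Gaussian density of the deviation between the logP predicted from the
#' unknown's retention time and the candidate's logP:
#' `dnorm(|logP_pred - logP_cand|, 0, sigma)`. Maximal at zero deviation and
#' symmetric in its sign.
#'
#' @param model An `rt_model`.
#' @param rt_unknown Retention time of the unknown in minutes.
#' @param logp_candidate Candidate logP value(s) from the model's configured
#'   source.
#' @return Raw score(s); `NA` logP values score 0 with a warning.
#' @export
#' @examples
#' rt_score_density(3.17, 1.65)  # 0.159 (3 d.p.)
rt_score <- function(model, rt_unknown, logp_candidate) {
  stopifnot(inherits(model, "rt_model"))
  rt_score_density(predict(model, rt_unknown), logp_candidate, model$sigma)
}

#' @rdname rt_score
#' @param logp_pred Predicted logP of the unknown.
#' @param sigma Gaussian standard deviation in logP units.
#' @export
rt_score_density <- function(logp_pred, logp_candidate, sigma = 1.5) {
  out <- stats::dnorm(abs(logp_pred - logp_candidate), mean = 0, sd = sigma)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " candidate(s) without logP; ",
            "retention term recorded as 0")
    out[is.na(out)] <- 0
  }
  out
}

#' Read a retention-time training file
#'
#' Delimited text with a `RetentionTime` column plus either a logP column
#' (name given by `logp_column`, e.g. `"UserLogP"`) or an `InChI` column
#' from which logP is computed internally.
#'
#' @param path Path to the training file (comma-, tab- or
#'   whitespace-separated with a header line).
#' @param logp_column Name of the logP column; `NULL` computes logP from the
#'   `InChI` column with the internal descriptor.
#' @return Data frame with columns `rt` and `logp`, plus attribute
#'   `logp_source`.
#' @export
read_rt_training <- function(path, logp_column = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"RetentionTime" %in% names(df)) {
    stop("training file lacks a 'RetentionTime' column: ", path)
  }
  if (!is.null(logp_column)) {
    if (!logp_column %in% names(df)) {
      stop("training file lacks column '", logp_column, "': ", path)
    }
    out <- data.frame(rt = as.numeric(df$RetentionTime),
                      logp = as.numeric(df[[logp_column]]))
    attr(out, "logp_source") <- logp_column
  } else {
    if (!"InChI" %in% names(df)) {
      stop("training file needs an 'InChI' column (or give logp_column): ",
           path)
    }
    out <- data.frame(rt = as.numeric(df$RetentionTime),
                      logp = compute_logp(df$InChI))
    attr(out, "logp_source") <- "internal"
  }
  out
}

#' Attach user-defined score columns
#'
#' Any numeric column of an external results table can be declared a scoring
#' term: it is normalized like the built-in terms and combined with its
#' configured weight.
#'
#' @param results Data frame of candidates (e.g. re-imported results).
#' @param score_columns Character vector of column names to use as terms.
#' @return Matrix of normalized term values (columns named as the terms),
#'   with the raw values as attribute `"raw"`.
#' @export
attach_user_scores <- function(results, score_columns) {
  raw <- matrix(0, nrow(results), length(score_columns),
                dimnames = list(NULL, score_columns))
  for (nm in score_columns) {
    if (!nm %in% names(results)) stop("missing user score column '", nm, "'")
    v <- results[[nm]]
    vn <- suppressWarnings(as.numeric(v))
    if (anyNA(vn)) {
      stop("non-numeric value in user score column '", nm, "', row ",
           which(is.na(vn))[1])
    }
    raw[, nm] <- vn
  }
  norm <- apply(raw, 2, normalize_terms)
  if (is.null(dim(norm))) {
    norm <- matrix(norm, nrow = nrow(raw), dimnames = dimnames(raw))
  }
  attr(norm, "raw") <- raw
  norm
}
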