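# Candidate-list filters applied before fragmentation, plus the post-scoring
# stereoisomer deduplication. Every filter preserves input order and is
# idempotent.

#' Remove unconnected candidates
#'
#' Salts and other multi-component records cannot have the correct neutral
#' mass and are dropped before fragmentation.
#'
#' @param candidates A `candidate_set`.
#' @return The filtered `candidate_set`.
#' @export
filter_unconnected <- function(candidates) {
  keep <- vapply(candidates, function(r) is_connected(r$structure),
                 logical(1))
  candidates[keep]
}

#' Element restriction filter
#'
#' Three modes: `only` keeps candidates whose element set is a subset of the
#' given elements; `must` requires all given elements to be present (others
#' allowed); `exclude` removes candidates containing any given element.
#' `must` and `exclude` combine conjunctively; `only` is mutually exclusive
#' with them. Implicit hydrogens count as element H.
#'
#' @param candidates A `candidate_set`.
#' @param only,must,exclude Character vectors of element symbols (or `NULL`).
#' @return The filtered `candidate_set`.
#' @export
filter_elements <- function(candidates, only = NULL, must = NULL,
                            exclude = NULL) {
  if (!is.null(only) && (!is.null(must) || !is.null(exclude))) {
    stop("'only' cannot be combined with 'must'/'exclude'")
  }
  if (length(intersect(must, exclude))) {
    stop("elements listed both as required and excluded: ",
         paste(intersect(must, exclude), collapse = ", "))
  }
  for (el in c(only, must, exclude)) {
    if (!el %in% names(.ISOTOPE_MASS)) stop("unknown element symbol: ", el)
  }
  keep <- vapply(candidates, function(r) {
    els <- names(r$formula)
    if (!is.null(only)) return(all(els %in% only))
    ok <- TRUE
    if (!is.null(must)) ok <- all(must %in% els)
    if (ok && !is.null(exclude)) ok <- !any(els %in% exclude)
    ok
  }, logical(1))
  candidates[keep]
}

#' SMARTS substructure filter
#'
#' Keeps a candidate when (the inclusion list is empty OR at least one
#' inclusion pattern matches) AND no exclusion pattern matches. Applied
#' prior to fragmentation.
#'
#' @param candidates A `candidate_set`.
#' @param include,exclude Character vectors of SMARTS patterns.
#' @return The filtered `candidate_set`.
#' @export
filter_substructures <- function(candidates, include = character(0),
                                 exclude = character(0)) {
  if (!length(include) && !length(exclude)) return(candidates)
  keep <- vapply(candidates, function(r) {
    inc_ok <- !length(include) ||
      substructure_match_count(r$structure, include) > 0L
    exc_ok <- !length(exclude) ||
      substructure_match_count(r$structure, exclude) == 0L
    inc_ok && exc_ok
  }, logical(1))
  candidates[keep]
}

#' Suspect-list inclusion filter
#'
#' Retains only candidates whose InChIKey first block appears in the suspect
#' set.
#'
#' @param candidates A `candidate_set`.
#' @param suspects Character vector of suspect InChIKey first blocks.
#' @return The filtered `candidate_set`.
#' @export
suspect_inclusion_filter <- function(candidates, suspects) {
  if (!length(suspects)) {
    warning("suspect inclusion filter enabled with an empty suspect list; ",
            "all candidates removed")
    return(candidates[logical(length(candidates))])
  }
  blocks <- candidate_first_blocks(candidates)
  candidates[blocks %in% suspects]
}

#' InChIKey first blocks of a candidate set
#'
#' Cached on each record after the first computation.
#'
#' @param candidates A `candidate_set`.
#' @return Character vector of 14-character first blocks.
#' @export
candidate_first_blocks <- function(candidates) {
  vapply(candidates, function(r) {
    fb <- r$properties[["InChIKeyBlock1"]]
    if (!is.null(fb)) return(as.character(fb))
    inchikey_first_block(r$structure)
  }, character(1))
}

#' Deduplicate stereoisomers by InChIKey first block
#'
#' After scoring, only the highest-scoring candidate of each group sharing
#' an InChIKey first block is retained (stereoisomers cannot usually be
#' distinguished by MS/MS). Score ties are broken by ascending identifier.
#'
#' @param candidates A scored `candidate_set` (records carry `final_score`).
#' @return The deduplicated `candidate_set`, input order preserved.
#' @export
dedupe_first_block <- function(candidates) {
  if (!length(candidates)) return(candidates)
  blocks <- candidate_first_blocks(candidates)
  scores <- vapply(candidates, function(r) {
    if (is.null(r$final_score)) stop("candidate '", r$id, "' is unscored")
    r$final_score
  }, numeric(1))
  ids <- candidate_ids(candidates)
  keep <- logical(length(candidates))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    best <- idx[order(-scores[idx], ids[idx])][1L]
    keep[best] <- TRUE
  }
  candidates[keep]
}
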