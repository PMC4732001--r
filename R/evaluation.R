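# Ranking metrics and weight-combination search.

.rank_parts <- function(scores, correct) {
  if (is.character(correct)) {
    if (is.null(names(scores))) stop("scores must be named to rank by id")
    correct <- match(correct, names(scores))
  }
  if (is.na(correct) || correct < 1L || correct > length(scores)) {
    stop("correct candidate not present in the score list")
  }
  sc <- scores[correct]
  list(better = sum(scores > sc),
       tied = sum(scores == sc),  # includes the correct candidate
       worse = sum(scores < sc),
       n = length(scores))
}

#' Pessimistic rank of the correct candidate
#'
#' The worst rank when the correct candidate ties with others: candidates
#' with a strictly greater score plus all tied candidates (including the
#' correct one itself).
#'
#' @param scores Final score per candidate (named vector when `correct` is
#'   an identifier).
#' @param correct Index or identifier of the correct candidate.
#' @return Integer rank >= 1.
#' @export
pessimistic_rank <- function(scores, correct) {
  p <- .rank_parts(scores, correct)
  as.integer(p$better + p$tied)
}

#' Expected rank under uniformly random tie-breaking
#'
#' @inheritParams pessimistic_rank
#' @return Rational rank >= 1 (mean rank over random orderings of the tied
#'   group).
#' @export
expected_rank <- function(scores, correct) {
  p <- .rank_parts(scores, correct)
  p$better + (p$tied + 1) / 2
}

#' Relative ranking position
#'
#' Normalized position of the correct candidate in the list: 1 is the best
#' possible result, 0 the worst. Ties count neither as better nor worse.
#' A single-candidate list is defined as 1 (the only possible position).
#'
#' @inheritParams pessimistic_rank
#' @return Value in `[0, 1]`.
#' @export
relative_ranking_position <- function(scores, correct) {
  p <- .rank_parts(scores, correct)
  if (p$n < 2L) {
    message("single-candidate list; relative ranking position defined as 1")
    return(1)
  }
  0.5 * (1 + (p$worse - p$better) / (p$n - 1))
}

#' Top-k counts over a set of queries
#'
#' @param ranks Numeric vector of per-query ranks (>= 1).
#' @param k Vector of thresholds.
#' @return Named integer vector: for each k, the number of queries with
#'   rank <= k.
#' @export
topk_counts <- function(ranks, k = c(1, 5, 10)) {
  stopifnot(all(ranks >= 1))
  setNames(vapply(k, function(kk) sum(ranks <= kk), numeric(1)),
           paste0("top", k))
}

#' Random draws from the weight simplex
#'
#' Uniform draws from the simplex of non-negative weights summing to 1,
#' using the sorted-uniform-spacings construction (equivalently a flat
#' Dirichlet). Used to explore how ranking performance depends on the
#' relative contribution of each evidence term.
#'
#' @param n_terms Number of weights per draw (>= 2).
#' @param n_draws Number of draws.
#' @param seed Integer seed for reproducibility.
#' @return `n_draws` x `n_terms` matrix; rows sum to 1.
#' @export
sample_weight_simplex <- function(n_terms, n_draws, seed = 1L) {
  stopifnot(n_terms >= 2L, n_draws >= 1L)
  set.seed(seed)
  t(vapply(seq_len(n_draws), function(i) {
    diff(c(0, sort(runif(n_terms - 1L)), 1))
  }, numeric(n_terms)))
}

#' Re-rank queries under alternative weight vectors
#'
#' For each weight vector, every query's candidates are re-combined from
#' their normalized score terms and the correct candidate's pessimistic rank
#' is recomputed; Top-k counts summarise each vector.
#'
#' @param term_matrices List with one normalized term matrix per query
#'   (rows = candidates, named columns = terms, rownames = identifiers).
#' @param correct_ids Character vector, one correct identifier per query.
#' @param weights Matrix of weight vectors (columns matching the term
#'   columns), e.g. from [sample_weight_simplex()].
#' @param k Top-k thresholds.
#' @return Data frame with one row per weight vector: the weights and the
#'   Top-k counts.
#' @export
weight_sweep <- function(term_matrices, correct_ids, weights,
                         k = c(1, 5, 10)) {
  stopifnot(length(term_matrices) == length(correct_ids))
  if (is.null(colnames(weights))) {
    colnames(weights) <- colnames(term_matrices[[1]])
  }
  rows <- lapply(seq_len(nrow(weights)), function(wi) {
    w <- weights[wi, ]
    ranks <- vapply(seq_along(term_matrices), function(qi) {
      tm <- term_matrices[[qi]]
      final <- as.numeric(tm[, colnames(weights), drop = FALSE] %*% w)
      names(final) <- rownames(tm)
      pessimistic_rank(final, correct_ids[qi])
    }, integer(1))
    c(as.list(w), as.list(topk_counts(ranks, k)))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Per-query evaluation report
#'
#' @param score_lists List of named final-score vectors, one per query.
#' @param correct_ids Character vector of correct identifiers.
#' @param k Top-k thresholds for the summary attribute.
#' @return Data frame with one row per query (pessimistic and expected
#'   rank, relative ranking position, candidate count); the summary row
#'   (Top-k counts, median/mean rank, mean RRP) is attached as attribute
#'   `"summary"`.
#' @export
evaluation_report <- function(score_lists, correct_ids, k = c(1, 5, 10)) {
  stopifnot(length(score_lists) == length(correct_ids))
  df <- do.call(rbind, lapply(seq_along(score_lists), function(i) {
    s <- score_lists[[i]]
    data.frame(
      query = i,
      correct = correct_ids[i],
      pessimistic_rank = pessimistic_rank(s, correct_ids[i]),
      expected_rank = expected_rank(s, correct_ids[i]),
      rrp = relative_ranking_position(s, correct_ids[i]),
      n_candidates = length(s)
    )
  }))
  attr(df, "summary") <- c(
    as.list(topk_counts(df$pessimistic_rank, k)),
    list(median_rank = stats::median(df$pessimistic_rank),
         mean_rank = mean(df$pessimistic_rank),
         mean_rrp = mean(df$rrp))
  )
  df
}
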