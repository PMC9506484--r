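# KSS-based ordinal ranking of candidate TICs within a transcript.

# Sort a scored candidate pool by descending KSS, ties broken 5'-most first,
# and attach ranks. method = "competition" gives shared min-ranks instead.
rank_pool <- function(pool, method = c("ordinal", "competition")) {
  method <- match.arg(method)
  if (!nrow(pool)) {
    pool$rank <- integer(0)
    pool$pool_size <- integer(0)
    return(pool)
  }
  ord <- order(-pool$kss, pool$position)
  pool <- pool[ord, , drop = FALSE]
  if (method == "ordinal") {
    pool$rank <- seq_len(nrow(pool))
  } else {
    pool$rank <- as.integer(rank(-pool$kss, ties.method = "min"))
  }
  pool$pool_size <- nrow(pool)
  rownames(pool) <- NULL
  pool
}

#' Rank candidate TICs upstream of the main TIC
#'
#' Scores every fully flanked ATG / near-cognate candidate strictly 5' of the
#' main TIC and assigns ordinal ranks by descending KSS: the candidate with
#' the highest score in the pool gets rank 1 (at most one rank-1 candidate
#' per transcript). Exact score ties (identical flanks) are broken in favour
#' of the 5'-most candidate, the one a scanning ribosome meets first.
#'
#' @param transcript a [transcript_record()].
#' @param matrix a [bits_matrix()].
#' @param codon_filter candidate codons; defaults to ATG plus the nine
#'   near-cognate codons.
#' @param method `"ordinal"` (unique ranks, default) or `"competition"`
#'   (ties share the smallest rank).
#' @return a data frame with columns `transcript_id`, `position` (0-based),
#'   `codon`, `kss`, `rank`, `pool_size`, `pool_kind` (`"upstream_all"`),
#'   sorted by rank. The number of candidates excluded for missing flanks is
#'   attached as attribute `n_excluded_partial`. An empty pool gives an empty
#'   data frame.
#' @export
rank_upstream <- function(transcript, matrix,
                          codon_filter = c("ATG", near_cognate_set()),
                          method = c("ordinal", "competition")) {
  method <- match.arg(method)
  cands <- enumerate_candidates(transcript, region = "UPSTREAM",
                                codon_filter = codon_filter, matrix = matrix)
  n_partial <- sum(!cands$has_full_flanks)
  pool <- cands[cands$has_full_flanks, , drop = FALSE]
  pool <- rank_pool(pool, method = method)
  out <- pool[, c("transcript_id", "position", "codon", "kss", "rank",
                  "pool_size"), drop = FALSE]
  out$pool_kind <- rep("upstream_all", nrow(out))
  attr(out, "n_excluded_partial") <- n_partial
  out
}

#' Rank the canonical TIC among all ATGs of its transcript
#'
#' The annotated main TIC (which must be an ATG) is ranked by KSS within the
#' pool of all fully flanked ATG codons anywhere in the transcript.
#'
#' @inheritParams rank_upstream
#' @return a one-row data frame in the same shape as [rank_upstream()] with
#'   `pool_kind = "full_atg"`, describing the main TIC. The full ranked pool
#'   is attached as attribute `pool`.
#' @export
rank_canonical <- function(transcript, matrix,
                           method = c("ordinal", "competition")) {
  method <- match.arg(method)
  main_codon <- substr(transcript$sequence, transcript$main_tic_start + 1L,
                       transcript$main_tic_start + 3L)
  if (main_codon != "ATG") {
    stop(sprintf(
      "transcript %s: main TIC codon is %s, not ATG; rank it against the upstream pool with rank_upstream()",
      transcript$id, main_codon))
  }
  cands <- enumerate_candidates(transcript, region = "FULL",
                                codon_filter = "ATG", matrix = matrix)
  main_row <- cands[cands$position == transcript$main_tic_start, , drop = FALSE]
  if (!nrow(main_row) || !main_row$has_full_flanks) {
    stop(sprintf("transcript %s: main TIC lacks a full 10-nt flank on each side",
                 transcript$id))
  }
  pool <- rank_pool(cands[cands$has_full_flanks, , drop = FALSE], method = method)
  out <- pool[pool$position == transcript$main_tic_start,
              c("transcript_id", "position", "codon", "kss", "rank",
                "pool_size"), drop = FALSE]
  out$pool_kind <- "full_atg"
  rownames(out) <- NULL
  attr(out, "pool") <- pool
  out
}

#' Look up the rank of a candidate by position
#'
#' @param position 0-based candidate start index.
#' @param ranked a ranked pool from [rank_upstream()] (or the `pool`
#'   attribute of [rank_canonical()]).
#' @return the candidate's rank (integer).
#' @export
rank_of <- function(position, ranked) {
  i <- match(as.integer(position), ranked$position)
  if (is.na(i)) {
    stop(sprintf("position %d is not in the ranked pool", as.integer(position)))
  }
  ranked$rank[i]
}
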