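# Cohort-level distributional comparisons: one-sided Mann-Whitney tests,
# random-codon KSS baseline, and positional summaries.

#' One-sided Mann-Whitney U test (first group stochastically greater)
#'
#' Tests H1: `x` tends to take larger values than `y`. For combined sample
#' sizes up to 16 without ties the exact null distribution of U is used;
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction. `u_statistic` is U for the `x` group.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param group_names labels for the two groups.
#' @return an object of class `mw_comparison`: a list with `group_names`,
#'   `n`, `medians`, `u_statistic`, `p_value_one_sided`, `alternative`,
#'   `outlier_removed`, `method`.
#' @export
mann_whitney_one_sided <- function(x, y, group_names = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("groups must not contain NA")
  exact <- (length(x) + length(y)) <= 16L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater",
                       exact = exact, correct = TRUE))
  structure(
    list(group_names = group_names,
         n = c(length(x), length(y)),
         medians = c(stats::median(x), stats::median(y)),
         u_statistic = unname(wt$statistic),
         p_value_one_sided = wt$p.value,
         alternative = "first group stochastically greater",
         outlier_removed = FALSE,
         method = wt$method),
    class = "mw_comparison")
}

#' @export
print.mw_comparison <- function(x, ...) {
  cat(sprintf("One-sided Mann-Whitney U test: %s > %s\n",
              x$group_names[1], x$group_names[2]))
  cat(sprintf("  n = %d vs %d;  medians = %s vs %s\n",
              x$n[1], x$n[2],
              format(x$medians[1], digits = 4),
              format(x$medians[2], digits = 4)))
  cat(sprintf("  U = %s;  one-sided p = %s%s\n",
              format(x$u_statistic), format(x$p_value_one_sided, digits = 4),
              if (x$outlier_removed) "  (lowest first-group value removed)" else ""))
  invisible(x)
}

#' Random-codon KSS baseline
#'
#' Draws `per_transcript` codon positions uniformly without replacement from
#' the fully flanked positions of each transcript (every position counts as a
#' codon start — the baseline is over arbitrary codons, not candidate starts)
#' and scores them. Transcripts too short to host a fully flanked codon are
#' skipped with a warning.
#'
#' @param transcripts a list of [transcript_record()]s.
#' @param matrix a [bits_matrix()].
#' @param per_transcript codons sampled per transcript (default 4).
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return a numeric vector of KSS values.
#' @export
sample_baseline <- function(transcripts, matrix, per_transcript = 4L,
                            seed = NULL) {
  stopifnot(inherits(matrix, "bits_matrix"))
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  for (tr in transcripts) {
    len <- nchar(tr$sequence)
    eligible <- if (len >= 23L) 10:(len - 13L) else integer(0)
    if (!length(eligible)) {
      warning(sprintf("transcript %s has no fully flanked position; skipped",
                      tr$id))
      next
    }
    k <- min(per_transcript, length(eligible))
    pos <- if (length(eligible) == 1L) eligible else
      sample(eligible, k, replace = FALSE)
    up <- substr(rep(tr$sequence, k), pos - 9L, pos)
    down <- substr(rep(tr$sequence, k), pos + 4L, pos + 13L)
    out <- c(out, score_flank_pairs(up, down, matrix, lenient = TRUE))
  }
  out
}

#' Compare noncanonical and canonical KSS distributions
#'
#' One-sided Mann-Whitney test of whether noncanonical TIC scores are
#' stochastically greater than canonical TIC scores, optionally after
#' removing the single lowest noncanonical value as an outlier (both
#' variants are reported in typical analyses; removal is never automatic).
#'
#' @param noncanonical,canonical numeric KSS vectors.
#' @param remove_lowest_noncanonical drop the minimum of the noncanonical
#'   group before testing (flagged in the result).
#' @return an `mw_comparison`.
#' @export
compare_kss_groups <- function(noncanonical, canonical,
                               remove_lowest_noncanonical = FALSE) {
  if (remove_lowest_noncanonical) {
    if (length(noncanonical) < 2L) {
      stop("cannot remove the lowest value from a singleton group")
    }
    noncanonical <- noncanonical[-which.min(noncanonical)]
  }
  res <- mann_whitney_one_sided(noncanonical, canonical,
                                group_names = c("noncanonical", "canonical"))
  res$outlier_removed <- remove_lowest_noncanonical
  res
}

#' Compare 5'UTR lengths between two transcript cohorts
#'
#' @param group_a,group_b lists of [transcript_record()]s.
#' @param group_names labels for the result.
#' @return an `mw_comparison` of the 5'UTR lengths (one-sided: group A
#'   longer).
#' @export
compare_utr_lengths <- function(group_a, group_b,
                                group_names = c("group_a", "group_b")) {
  la <- vapply(group_a, utr5_length, integer(1))
  lb <- vapply(group_b, utr5_length, integer(1))
  mann_whitney_one_sided(la, lb, group_names = group_names)
}

#' Positional summary of identified TICs
#'
#' For each TIC: its distance from the transcript 5' end and the number of
#' ATG plus near-cognate codons strictly upstream of it (any reading frame).
#' For the cohort: the fraction of transcripts whose 5'-most ATG is the
#' annotated canonical TIC, and median transcript / 5'UTR lengths.
#'
#' @param tics a data frame with columns `transcript_id` and `position`
#'   (0-based), e.g. the `kept` table of [apply_filters()].
#' @param transcripts a list of [transcript_record()]s covering every TIC's
#'   transcript (and defining the cohort for the per-transcript fractions).
#' @return an object of class `positional_summary`: a list with `per_tic`
#'   (data frame with `transcript_id`, `position`, `dist_5prime`,
#'   `n_upstream_candidates`), `fraction_first_atg_canonical`,
#'   `median_upstream_candidates`, `median_transcript_length`,
#'   `median_utr5_length`.
#' @export
summarize_positions <- function(tics, transcripts) {
  if (is.null(names(transcripts)) || !all(nzchar(names(transcripts)))) {
    names(transcripts) <- vapply(transcripts, function(t) t$id, character(1))
  }
  missing_ids <- setdiff(unique(tics$transcript_id), names(transcripts))
  if (length(missing_ids)) {
    stop("TIC table references transcripts not supplied: ",
         paste(missing_ids, collapse = ", "))
  }
  filt <- c("ATG", near_cognate_set())
  per_tic <- if (nrow(tics)) {
    do.call(rbind, lapply(seq_len(nrow(tics)), function(i) {
      tr <- transcripts[[tics$transcript_id[i]]]
      p <- as.integer(tics$position[i])
      cands <- enumerate_candidates(tr, region = "FULL", codon_filter = filt)
      data.frame(transcript_id = tr$id, position = p, dist_5prime = p,
                 n_upstream_candidates = sum(cands$position < p),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(transcript_id = character(0), position = integer(0),
               dist_5prime = integer(0), n_upstream_candidates = integer(0),
               stringsAsFactors = FALSE)
  }
  first_atg_canonical <- vapply(transcripts, function(tr) {
    atgs <- enumerate_candidates(tr, region = "FULL", codon_filter = "ATG")
    nrow(atgs) > 0L && atgs$position[1L] == tr$main_tic_start
  }, logical(1))
  lens <- vapply(transcripts, function(tr) nchar(tr$sequence), integer(1))
  utrs <- vapply(transcripts, utr5_length, integer(1))
  structure(
    list(per_tic = per_tic,
         fraction_first_atg_canonical = mean(first_atg_canonical),
         median_upstream_candidates =
           if (nrow(per_tic)) stats::median(per_tic$n_upstream_candidates) else NA_real_,
         median_transcript_length = stats::median(lens),
         median_utr5_length = stats::median(utrs)),
    class = "positional_summary")
}

#' @export
print.positional_summary <- function(x, ...) {
  cat("Positional summary\n")
  cat(sprintf("  TICs summarised:                 %d\n", nrow(x$per_tic)))
  cat(sprintf("  median upstream ATG/near-cognate codons per TIC: %s\n",
              format(x$median_upstream_candidates)))
  cat(sprintf("  fraction of transcripts with 5'-most ATG = canonical TIC: %.3f\n",
              x$fraction_first_atg_canonical))
  cat(sprintf("  median transcript length: %s nt; median 5'UTR length: %s nt\n",
              format(x$median_transcript_length), format(x$median_utr5_length)))
  invisible(x)
}
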