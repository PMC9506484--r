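# Transcript records, codon-context extraction and candidate TIC enumeration.

#' Construct an annotated transcript record
#'
#' An mRNA-sense transcript sequence with the annotated start of its main
#' coding sequence. Coordinates are 0-based internally (the 5'UTR is the
#' prefix of length `main_tic_start`); all user-facing report writers emit
#' 1-based positions.
#'
#' @param id transcript identifier.
#' @param sequence nucleotide string (A/C/G/T, N tolerated; scored leniently
#'   or rejected at scoring time).
#' @param main_tic_start 0-based index of the first nucleotide of the
#'   annotated main translation initiation codon. The codon found there is
#'   recorded as-is and is not forced to be ATG.
#' @param cds_end optional 0-based exclusive end of the annotated CDS; must
#'   exceed `main_tic_start` by a multiple of 3.
#' @param gene optional gene symbol.
#' @return an object of class `transcript_record`.
#' @export
transcript_record <- function(id, sequence, main_tic_start, cds_end = NA,
                              gene = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(BASES, "N"))
  if (length(bad)) {
    stop(sprintf("transcript %s contains characters outside A/C/G/T/N: %s",
                 id, paste(bad, collapse = ", ")))
  }
  main_tic_start <- as.integer(main_tic_start)
  len <- nchar(sequence)
  if (is.na(main_tic_start) || main_tic_start < 0L || main_tic_start > len - 3L) {
    stop(sprintf("transcript %s: main_tic_start must lie in [0, length - 3]", id))
  }
  if (!is.na(cds_end)) {
    cds_end <- as.integer(cds_end)
    if (cds_end <= main_tic_start || cds_end > len ||
        (cds_end - main_tic_start) %% 3L != 0L) {
      stop(sprintf(
        "transcript %s: cds_end must exceed main_tic_start by a positive multiple of 3 and fit the sequence", id))
    }
  } else {
    cds_end <- NA_integer_
  }
  structure(list(id = id, gene = gene, sequence = sequence,
                 main_tic_start = main_tic_start, cds_end = cds_end),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s%s: %d nt, 5'UTR %d nt, main TIC %s at %d (0-based)%s\n",
              x$id,
              if (!is.na(x$gene)) paste0(" (", x$gene, ")") else "",
              nchar(x$sequence), x$main_tic_start,
              substr(x$sequence, x$main_tic_start + 1L, x$main_tic_start + 3L),
              x$main_tic_start,
              if (!is.na(x$cds_end)) sprintf(", CDS end %d", x$cds_end) else ""))
  invisible(x)
}

#' The nine near-cognate start codons
#'
#' Codons at Hamming distance exactly 1 from ATG; the noncanonical initiation
#' codons considered throughout the package.
#'
#' @return a character vector of 9 codons, sorted.
#' @export
near_cognate_set <- function() {
  out <- character(0)
  atg <- c("A", "T", "G")
  for (i in 1:3) {
    for (nt in setdiff(BASES, atg[i])) {
      cod <- atg
      cod[i] <- nt
      out <- c(out, paste(cod, collapse = ""))
    }
  }
  sort(unique(out))
}

#' The four most commonly used near-cognate start codons
#'
#' The near-cognate codons with the most stable ribosome base pairing, hence
#' most often observed to initiate: GTG, CTG, ACG and TTG. Useful as a
#' stricter `codon_filter` for scanning.
#'
#' @return a character vector of 4 codons.
#' @export
common_near_cognate_set <- function() {
  c("GTG", "CTG", "ACG", "TTG")
}

#' Extract the codon context at a transcript position
#'
#' @param transcript a [transcript_record()].
#' @param position 0-based start index of the codon; both 10-nt flanks must
#'   fit inside the sequence (`position >= 10`,
#'   `position + 13 <= nchar(sequence)`), otherwise an `insufficient_flank`
#'   error is raised.
#' @param lenient passed to [codon_context()].
#' @return a [codon_context()].
#' @export
extract_context <- function(transcript, position, lenient = FALSE) {
  stopifnot(inherits(transcript, "transcript_record"))
  position <- as.integer(position)
  len <- nchar(transcript$sequence)
  if (position < 10L || position + 13L > len) {
    stop(structure(
      class = c("insufficient_flank", "error", "condition"),
      list(message = sprintf(
        "transcript %s: position %d lacks a full 10-nt flank on each side (sequence length %d)",
        transcript$id, position, len),
        call = sys.call(-1))))
  }
  s <- transcript$sequence
  codon_context(substr(s, position - 9L, position),
                substr(s, position + 1L, position + 3L),
                substr(s, position + 4L, position + 13L),
                lenient = lenient)
}

# Region label of a candidate start position (0-based), by its first
# nucleotide: 5'UTR before the main TIC, CDS from it to cds_end, UTR3 after.
candidate_region <- function(position, main_tic_start, cds_end) {
  r <- ifelse(position < main_tic_start, "UTR5", "CDS")
  if (!is.na(cds_end)) r[position >= cds_end] <- "UTR3"
  r
}

#' Enumerate candidate initiation codons in a transcript
#'
#' Scans every position (all three reading frames) of the requested region
#' for 3-mers in `codon_filter`. `region = "UPSTREAM"` keeps candidates whose
#' first nucleotide lies strictly 5' of the main TIC (a candidate overlapping
#' the main TIC boundary still counts as upstream, since a scanning ribosome
#' reaches it first); `"UTR5"` requires the whole codon inside the 5'UTR;
#' `"FULL"` scans everything. Candidates without a complete 10-nt flank on
#' each side are returned with `has_full_flanks = FALSE` and are excluded
#' from scoring and ranking by default.
#'
#' @param transcript a [transcript_record()].
#' @param region one of `"FULL"`, `"UPSTREAM"`, `"UTR5"`.
#' @param codon_filter non-empty character vector of 3-mers; defaults to ATG
#'   plus the nine near-cognate codons.
#' @param matrix optional [bits_matrix()]; when supplied, fully-flanked
#'   candidates are scored into the `kss` column.
#' @param lenient passed to the scorer.
#' @param pad if `TRUE` (and a matrix is given), candidates lacking full
#'   flanks are scored too, with out-of-sequence positions contributing zero
#'   bits; `has_full_flanks` still records their status.
#' @return a data frame with columns `transcript_id`, `position` (0-based),
#'   `codon`, `region`, `is_atg`, `is_near_cognate`, `has_full_flanks`,
#'   `kss`, ordered by position.
#' @export
enumerate_candidates <- function(transcript,
                                 region = c("FULL", "UPSTREAM", "UTR5"),
                                 codon_filter = c("ATG", near_cognate_set()),
                                 matrix = NULL, lenient = FALSE, pad = FALSE) {
  stopifnot(inherits(transcript, "transcript_record"))
  region <- match.arg(region)
  codon_filter <- toupper(codon_filter)
  if (!length(codon_filter)) stop("codon_filter must be non-empty")
  len <- nchar(transcript$sequence)
  empty <- data.frame(transcript_id = character(0), position = integer(0),
                      codon = character(0), region = character(0),
                      is_atg = logical(0), is_near_cognate = logical(0),
                      has_full_flanks = logical(0), kss = numeric(0),
                      stringsAsFactors = FALSE)
  if (len < 3L) return(empty)
  pos <- 0:(len - 3L)
  codons <- substring(transcript$sequence, pos + 1L, pos + 3L)
  keep <- codons %in% codon_filter
  if (region == "UPSTREAM") keep <- keep & pos < transcript$main_tic_start
  if (region == "UTR5")     keep <- keep & pos + 3L <= transcript$main_tic_start
  pos <- pos[keep]
  codons <- codons[keep]
  if (!length(pos)) return(empty)
  nc <- near_cognate_set()
  out <- data.frame(
    transcript_id = transcript$id,
    position = pos,
    codon = codons,
    region = candidate_region(pos, transcript$main_tic_start, transcript$cds_end),
    is_atg = codons == "ATG",
    is_near_cognate = codons %in% nc,
    has_full_flanks = pos >= 10L & pos + 13L <= len,
    kss = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(matrix)) {
    out <- score_candidates(out, transcript, matrix, lenient = lenient, pad = pad)
  }
  out
}

#' Score enumerated candidates
#'
#' Fills the `kss` column of a candidate table for one transcript. Fully
#' flanked candidates are always scored; with `pad = TRUE`, partially flanked
#' candidates are scored with missing positions contributing zero bits.
#'
#' @param candidates a data frame from [enumerate_candidates()].
#' @param transcript the matching [transcript_record()].
#' @param matrix a [bits_matrix()].
#' @inheritParams enumerate_candidates
#' @return the candidate data frame with `kss` filled in.
#' @export
score_candidates <- function(candidates, transcript, matrix,
                             lenient = FALSE, pad = FALSE) {
  stopifnot(inherits(transcript, "transcript_record"),
            inherits(matrix, "bits_matrix"))
  if (!nrow(candidates)) return(candidates)
  if (any(candidates$transcript_id != transcript$id)) {
    stop("candidate table does not belong to transcript ", transcript$id)
  }
  s <- transcript$sequence
  len <- nchar(s)
  todo <- candidates$has_full_flanks | pad
  if (any(todo)) {
    p <- candidates$position[todo]
    pad_chr <- function(x, width, left) {
      short <- width - nchar(x)
      filler <- vapply(pmax(short, 0L), function(k) strrep("-", k), character(1))
      if (left) paste0(filler, x) else paste0(x, filler)
    }
    up <- substr(rep(s, length(p)), pmax(p - 9L, 1L), p)
    down <- substr(rep(s, length(p)), p + 4L, pmin(p + 13L, len))
    up <- pad_chr(up, 10L, left = TRUE)
    down <- pad_chr(down, 10L, left = FALSE)
    candidates$kss[todo] <- score_flank_pairs(up, down, matrix,
                                              lenient = lenient || pad)
  }
  candidates
}

#' 5'UTR length of a transcript
#'
#' The number of nucleotides strictly before the annotated main TIC, i.e. the
#' 0-based main TIC start itself.
#'
#' @param transcript a [transcript_record()].
#' @return a non-negative integer.
#' @export
utr5_length <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_record"))
  transcript$main_tic_start
}
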