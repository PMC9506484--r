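# Kozak Similarity Score model: bits matrix container + Eq.-style scoring.

#' @keywords internal
BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a validated bits matrix
#'
#' A bits matrix holds, for each of the 20 context positions (ten nucleotides
#' left of a codon, positions 1-10 read 5' to 3', and ten nucleotides right of
#' it, positions 11-20), a non-negative "height" for each nucleotide. The
#' Kozak Similarity Score of a codon context is the sum of the heights of the
#' observed context nucleotides divided by the maximum attainable sum
#' (`kss_max()`).
#'
#' @param heights numeric 20 x 4 matrix; rows are positions 1-20, columns
#'   `A`, `C`, `G`, `T`.
#' @param source_label free-text provenance of the values.
#' @return an object of class `bits_matrix` with elements `heights`,
#'   `source_label` and `kss_bits_max`.
#' @seealso [load_bits_matrix()], [default_kozak_matrix()], [kss_score()]
#' @export
bits_matrix <- function(heights, source_label = "user-supplied") {
  heights <- as.matrix(heights)
  if (!is.numeric(heights)) {
    stop("bits matrix heights must be numeric")
  }
  if (nrow(heights) != 20L || ncol(heights) != 4L) {
    stop(sprintf("bits matrix must be 20 positions x 4 nucleotides, got %d x %d",
                 nrow(heights), ncol(heights)))
  }
  if (is.null(colnames(heights))) colnames(heights) <- BASES
  if (!identical(sort(colnames(heights)), BASES)) {
    stop("bits matrix columns must be named A, C, G, T")
  }
  heights <- heights[, BASES, drop = FALSE]
  rownames(heights) <- as.character(1:20)
  for (p in 1:20) {
    for (nt in BASES) {
      v <- heights[p, nt]
      if (is.na(v)) {
        stop(sprintf("non-numeric bits value at position %d, nucleotide %s", p, nt))
      }
      if (v < 0) {
        stop(sprintf("negative bits value at position %d, nucleotide %s", p, nt))
      }
    }
    if (max(heights[p, ]) <= 0) {
      stop(sprintf("all four heights are zero at position %d (maximum attainable sum would lose this position)", p))
    }
  }
  structure(
    list(heights = heights,
         source_label = source_label,
         kss_bits_max = sum(apply(heights, 1L, max))),
    class = "bits_matrix"
  )
}

#' @export
print.bits_matrix <- function(x, ...) {
  cat("Bits matrix (20 positions x A/C/G/T)\n")
  cat("  source:      ", x$source_label, "\n", sep = "")
  cat("  kss_bits_max:", format(x$kss_bits_max), "\n")
  cat("  consensus:   ",
      paste(BASES[apply(x$heights[1:10, ], 1L, which.max)], collapse = ""),
      " [codon] ",
      paste(BASES[apply(x$heights[11:20, ], 1L, which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Load a bits matrix from a table
#'
#' Reads a tab-separated table (or an equivalent data frame) with columns
#' `position`, `A`, `C`, `G`, `T` and rows for positions 1-20. Positions 1-10
#' are the ten nucleotides 5' of the codon (left to right), positions 11-20
#' the ten nucleotides 3' of it. Lines starting with `#` are ignored.
#'
#' @param x path to a TSV file, or a data frame with the columns above.
#' @param source_label provenance recorded on the returned matrix; defaults
#'   to the file path.
#' @return a [bits_matrix()].
#' @export
load_bits_matrix <- function(x, source_label = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (is.null(source_label)) source_label <- x
    x <- utils::read.delim(x, comment.char = "#", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  }
  if (is.null(source_label)) source_label <- "user-supplied table"
  x <- as.data.frame(x)
  need <- c("position", BASES)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("bits matrix table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(as.character(x$position)))
  if (any(is.na(pos))) stop("non-integer position label in bits matrix table")
  if (!setequal(pos, 1:20) || anyDuplicated(pos)) {
    miss <- setdiff(1:20, pos)
    if (length(miss)) {
      stop("bits matrix table is missing position ", paste(miss, collapse = ", "))
    }
    stop("bits matrix table has duplicated or out-of-range positions")
  }
  h <- matrix(NA_real_, 20L, 4L, dimnames = list(1:20, BASES))
  for (i in seq_len(nrow(x))) {
    p <- pos[i]
    for (nt in BASES) {
      v <- suppressWarnings(as.numeric(as.character(x[[nt]][i])))
      if (is.na(v)) {
        stop(sprintf("non-numeric bits value at position %d, nucleotide %s", p, nt))
      }
      h[p, nt] <- v
    }
  }
  bits_matrix(h, source_label = source_label)
}

#' Packaged default Kozak-context bits matrix
#'
#' The values behind the published Kozak Similarity Score are not public, so
#' the package ships its own consensus-motif height model: each position has a
#' modal nucleotide whose height encodes both how preferred the nucleotide is
#' and how much the position matters for initiation. The strong purine
#' preference sits at position 8 (the classic -3 position, A over G), the
#' position immediately 5' of the codon is A-leaning, and position 11 (the
#' first nucleotide after the codon, +4 for an ATG) strongly prefers G.
#' Positions far from the codon carry low, nearly flat heights.
#'
#' Scores computed with this matrix are internally consistent and span
#' [0, 1], but are not numerically identical to scores from the original
#' (unpublished) matrix; replace it with [load_bits_matrix()] to reproduce
#' external scores.
#'
#' @return a [bits_matrix()].
#' @export
default_kozak_matrix <- function() {
  h <- matrix(c(
    # A     C     G     T        position (codon-relative)
    0.08, 0.25, 0.10, 0.06,   #  1  (-10)
    0.07, 0.25, 0.11, 0.05,   #  2  (-9)
    0.09, 0.10, 0.25, 0.06,   #  3  (-8)
    0.08, 0.25, 0.09, 0.07,   #  4  (-7)
    0.10, 0.12, 0.40, 0.06,   #  5  (-6)
    0.11, 0.40, 0.12, 0.05,   #  6  (-5)
    0.12, 0.40, 0.08, 0.06,   #  7  (-4)
    0.60, 0.06, 0.30, 0.04,   #  8  (-3)  strong purine, A > G
    0.10, 0.40, 0.12, 0.05,   #  9  (-2)
    0.40, 0.08, 0.12, 0.05,   # 10  (-1)  A-leaning
    0.15, 0.10, 0.60, 0.05,   # 11  (+4)  strong G
    0.10, 0.40, 0.12, 0.06,   # 12  (+5)
    0.08, 0.40, 0.12, 0.05,   # 13  (+6)
    0.25, 0.09, 0.10, 0.06,   # 14  (+7)
    0.07, 0.25, 0.10, 0.05,   # 15  (+8)
    0.08, 0.10, 0.25, 0.06,   # 16  (+9)
    0.09, 0.25, 0.08, 0.06,   # 17  (+10)
    0.06, 0.25, 0.10, 0.07,   # 18  (+11)
    0.08, 0.10, 0.25, 0.05,   # 19  (+12)
    0.07, 0.25, 0.09, 0.06    # 20  (+13)
  ), nrow = 20L, byrow = TRUE, dimnames = list(1:20, BASES))
  bits_matrix(
    h,
    source_label = paste("kozakscan packaged consensus-motif heights",
                         "(nucleotide preference x positional impact;",
                         "codon-relative positions -10..-1, +4..+13)")
  )
}

#' Maximum attainable bits sum of a matrix
#'
#' The sum over the 20 context positions of the per-position maximum height;
#' the normalising constant of [kss_score()].
#'
#' @param matrix a [bits_matrix()].
#' @return a positive scalar.
#' @export
kss_max <- function(matrix) {
  stopifnot(inherits(matrix, "bits_matrix"))
  matrix$kss_bits_max
}

#' Construct a codon context
#'
#' The unit the score is computed on: a codon together with exactly ten
#' flanking nucleotides on each side, in transcript order.
#'
#' @param upstream 10-character nucleotide string 5' of the codon.
#' @param codon 3-character nucleotide string.
#' @param downstream 10-character nucleotide string 3' of the codon.
#' @param lenient if `TRUE`, characters outside A/C/G/T are tolerated in the
#'   flanks (they score zero bits); otherwise they are an error at scoring
#'   time.
#' @return an object of class `codon_context`.
#' @export
codon_context <- function(upstream, codon, downstream, lenient = FALSE) {
  for (part in list(c("upstream flank", upstream, 10L),
                    c("codon", codon, 3L),
                    c("downstream flank", downstream, 10L))) {
    if (!is.character(part[[2]]) || length(part[[2]]) != 1L ||
        nchar(part[[2]]) != as.integer(part[[3]])) {
      stop(sprintf("%s must be a single %s-character string", part[[1]], part[[3]]))
    }
  }
  upstream <- toupper(upstream); codon <- toupper(codon)
  downstream <- toupper(downstream)
  if (!lenient) {
    bad <- setdiff(strsplit(paste0(upstream, codon, downstream), "")[[1]], BASES)
    if (length(bad)) {
      stop("codon context contains characters outside A/C/G/T: ",
           paste(unique(bad), collapse = ", "),
           " (use lenient = TRUE to score them as zero bits)")
    }
  }
  structure(list(upstream = upstream, codon = codon, downstream = downstream,
                 lenient = lenient),
            class = "codon_context")
}

#' @export
print.codon_context <- function(x, ...) {
  cat(x$upstream, " [", x$codon, "] ", x$downstream, "\n", sep = "")
  invisible(x)
}

# Vectorised scoring core shared by kss_score() and the scanners.
# up/down: character vectors of 10-nt flanks. Returns numeric scores.
score_flank_pairs <- function(up, down, matrix, lenient = FALSE) {
  n <- length(up)
  stopifnot(length(down) == n)
  if (n == 0L) return(numeric(0))
  chars <- strsplit(paste0(up, down), "", fixed = TRUE)
  idx <- match(unlist(chars), BASES)
  if (anyNA(idx) && !lenient) {
    bad <- unique(unlist(chars)[is.na(idx)])
    stop("flank contains characters outside A/C/G/T: ",
         paste(bad, collapse = ", "))
  }
  posidx <- rep.int(1:20, n)
  v <- numeric(length(idx))
  ok <- !is.na(idx)
  v[ok] <- matrix$heights[cbind(posidx[ok], idx[ok])]
  colSums(base::matrix(v, nrow = 20L)) / matrix$kss_bits_max
}

#' Kozak Similarity Score of a codon context
#'
#' Sums the matrix heights of the twenty flanking nucleotides (positions 1-10
#' read the upstream flank left to right, 11-20 the downstream flank) and
#' divides by [kss_max()]. The codon's own three nucleotides do not enter the
#' sum, so the score depends only on the context. The result always lies in
#' \[0, 1\], reaching 1 only when every flank position carries a
#' maximal-height nucleotide.
#'
#' @param context a [codon_context()].
#' @param matrix a [bits_matrix()].
#' @param lenient if `TRUE`, non-A/C/G/T flank characters contribute zero
#'   bits instead of raising an error. Defaults to the context's own setting.
#' @return a scalar in \[0, 1\].
#' @export
kss_score <- function(context, matrix, lenient = NULL) {
  stopifnot(inherits(context, "codon_context"), inherits(matrix, "bits_matrix"))
  if (is.null(lenient)) lenient <- isTRUE(context$lenient)
  score_flank_pairs(context$upstream, context$downstream, matrix,
                    lenient = lenient)
}
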