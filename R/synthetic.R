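# Synthetic transcript cohorts with planted TICs in contexts of controllable
# Kozak similarity; the benchmark substrate for every other module.

ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# Replace the middle nucleotide of a 3-mer with C; turns any stop codon
# (TAA/TAG/TGA) into a non-stop and ATG into ACG. Used to keep planted
# reading frames open without re-drawing whole contexts.
defuse_codon <- function(chars3) {
  chars3[2] <- "C"
  chars3
}

#' Specify a synthetic transcript cohort
#'
#' Parameters of [generate_cohort()]. 5'UTR lengths are log-normal,
#' parameterised by their median (so cohorts emulating the two observed
#' regimes plug in medians of 205 nt for the cancer-like and 112 nt for the
#' non-cancer-like group directly) with a log-scale spread. Planted TICs are
#' placed at uniform positions in the 5'UTR with softmax-sampled contexts
#' whose similarity to the matrix consensus grows with
#' `context_concentration` (0 = uniform background, large = consensus).
#'
#' @param n_transcripts number of transcripts.
#' @param utr_length_median median 5'UTR length in nucleotides.
#' @param utr_length_spread log-scale standard deviation of UTR lengths.
#' @param cds_length_range min/max CDS length in nucleotides (rounded to
#'   codons; minimum 24).
#' @param planted_tic_codons codons planted upstream per transcript (one TIC
#'   per entry; `character(0)` plants none). Stop codons are not allowed.
#' @param context_concentration softmax concentration of planted-TIC
#'   contexts (>= 0).
#' @param main_tic_concentration softmax concentration of the main ATG's
#'   context.
#' @param background_composition probabilities of A, C, G, T in background
#'   sequence.
#' @param utr3_length length of the trailing 3'UTR stub.
#' @param seed optional integer seed for full reproducibility.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_transcripts,
                        utr_length_median = 205,
                        utr_length_spread = 0.55,
                        cds_length_range = c(300, 900),
                        planted_tic_codons = "CTG",
                        context_concentration = 10,
                        main_tic_concentration = 10,
                        background_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                        utr3_length = 25L,
                        seed = NULL) {
  n_transcripts <- as.integer(n_transcripts)
  stopifnot(n_transcripts >= 1L, utr_length_median > 0,
            utr_length_spread >= 0, length(cds_length_range) == 2L,
            cds_length_range[1] >= 24, cds_length_range[2] >= cds_length_range[1],
            context_concentration >= 0, main_tic_concentration >= 0,
            length(background_composition) == 4L,
            all(background_composition >= 0), utr3_length >= 0L)
  if (abs(sum(background_composition) - 1) > 1e-8) {
    stop("background_composition must sum to 1")
  }
  planted_tic_codons <- toupper(planted_tic_codons)
  if (length(planted_tic_codons)) {
    stopifnot(all(nchar(planted_tic_codons) == 3L),
              all(planted_tic_codons %in% ALL_CODONS))
    if (any(planted_tic_codons %in% STOP_CODONS)) {
      stop("planted TIC codons must not be stop codons")
    }
  }
  structure(list(n_transcripts = n_transcripts,
                 utr_length_median = utr_length_median,
                 utr_length_spread = utr_length_spread,
                 cds_length_range = as.numeric(cds_length_range),
                 planted_tic_codons = planted_tic_codons,
                 context_concentration = context_concentration,
                 main_tic_concentration = main_tic_concentration,
                 background_composition = unname(background_composition),
                 utr3_length = as.integer(utr3_length),
                 seed = seed),
            class = "cohort_spec")
}

#' Sample codon-context flanks from a bits matrix
#'
#' At each of the 20 context positions a nucleotide is drawn with probability
#' proportional to `exp(concentration * height)`: concentration 0 gives
#' uniform draws, and as the concentration grows the per-position
#' maximal-height nucleotide dominates, so expected KSS increases
#' monotonically from the uniform mean towards 1.
#'
#' @param matrix a [bits_matrix()].
#' @param concentration non-negative softmax concentration.
#' @param n number of flank pairs to draw.
#' @return a data frame with character columns `upstream` and `downstream`
#'   (10 nt each).
#' @export
sample_context <- function(matrix, concentration, n = 1L) {
  stopifnot(inherits(matrix, "bits_matrix"), concentration >= 0, n >= 0)
  if (n == 0L) {
    return(data.frame(upstream = character(0), downstream = character(0),
                      stringsAsFactors = FALSE))
  }
  w <- exp(concentration * matrix$heights)
  probs <- w / rowSums(w)
  draws <- vapply(1:20, function(p) sample(BASES, n, replace = TRUE,
                                           prob = probs[p, ]),
                  character(n))
  draws <- base::matrix(draws, nrow = n)   # n x 20
  up <- apply(draws[, 1:10, drop = FALSE], 1L, paste, collapse = "")
  down <- apply(draws[, 11:20, drop = FALSE], 1L, paste, collapse = "")
  data.frame(upstream = up, downstream = down, stringsAsFactors = FALSE)
}

draw_utr_length <- function(median, spread, floor_nt, tries = 100L) {
  for (i in seq_len(tries)) {
    l <- as.integer(round(stats::rlnorm(1, meanlog = log(median),
                                        sdlog = spread)))
    if (l >= floor_nt) return(l)
  }
  NA_integer_
}

# Place k planted-TIC starts (0-based) in a UTR of length utr:
# >= 10 nt of flank on the left, a 28-nt downstream reserve (flank + open
# reading runway) clear of the main TIC's own upstream flank, and >= 35 nt
# between TICs so windows never overlap.
place_planted <- function(utr, k, tries = 200L) {
  lo <- 10L; hi <- utr - 28L
  if (hi < lo || (hi - lo) < 35L * (k - 1L)) return(NULL)
  cand <- lo:hi
  for (i in seq_len(tries)) {
    p <- sort(cand[sample.int(length(cand), k, replace = FALSE)])
    if (k == 1L || all(diff(p) >= 35L)) return(p)
  }
  NULL
}

#' Generate a synthetic transcript cohort with planted TICs
#'
#' Per transcript: draws a 5'UTR length from the spec's log-normal
#' (re-drawing as needed so planted TICs fit; an error names the transcript
#' if the spec makes that impossible), fills background sequence from the
#' spec's composition, plants a main ATG in a high-concentration context
#' followed by an in-frame, stop-free CDS ending in a stop codon, and plants
#' the requested upstream TICs at uniform non-overlapping 5'UTR positions
#' with contexts at the spec concentration. The five codons downstream of
#' every planted TIC are kept free of stops (and the first of them free of
#' ATG) so each planted TIC supports an N-terminal peptide. Fully
#' reproducible for a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param matrix the [bits_matrix()] contexts are sampled from; defaults to
#'   [default_kozak_matrix()].
#' @return a list with `transcripts` (named list of [transcript_record()]s),
#'   `truth` (data frame: `transcript_id`, `position` (0-based), `codon`,
#'   `concentration`, `main_tic_start`) and `spec`.
#' @export
generate_cohort <- function(spec, matrix = default_kozak_matrix()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(matrix, "bits_matrix"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_transcripts
  k <- length(spec$planted_tic_codons)
  comp <- spec$background_composition
  floor_nt <- if (k > 0L) 38L + 35L * (k - 1L) else 12L

  main_ctx <- sample_context(matrix, spec$main_tic_concentration, n)
  planted_ctx <- sample_context(matrix, spec$context_concentration, n * k)

  cds_codon_counts <- seq.int(ceiling(spec$cds_length_range[1] / 3),
                              floor(spec$cds_length_range[2] / 3))
  cds_lens <- 3L * cds_codon_counts[sample.int(length(cds_codon_counts), n,
                                               replace = TRUE)]

  transcripts <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    utr <- draw_utr_length(spec$utr_length_median, spec$utr_length_spread,
                           floor_nt)
    slots <- NULL
    if (k > 0L) {
      for (try in 1:100) {
        if (!is.na(utr)) slots <- place_planted(utr, k)
        if (!is.null(slots)) break
        utr <- draw_utr_length(spec$utr_length_median, spec$utr_length_spread,
                               floor_nt)
      }
      if (is.null(slots)) {
        stop(sprintf(
          "transcript %d: 5'UTR too short to host %d planted TIC(s) under this spec",
          i, k))
      }
    }
    if (is.na(utr)) {
      stop(sprintf("transcript %d: could not draw a 5'UTR of at least %d nt under this spec",
                   i, floor_nt))
    }
    utr_chars <- sample(BASES, utr, replace = TRUE, prob = comp)
    # main TIC upstream flank occupies the last 10 nt of the UTR
    utr_chars[(utr - 9L):utr] <- strsplit(main_ctx$upstream[i], "")[[1]]

    if (k > 0L) {
      for (j in seq_len(k)) {
        p <- slots[j]                     # 0-based TIC start
        ctx <- planted_ctx[(i - 1L) * k + j, ]
        down <- strsplit(ctx$downstream, "")[[1]]
        # keep the planted reading frame open: codons 2-4 sit in the flank
        for (cs in c(1L, 4L, 7L)) {
          cod <- down[cs:(cs + 2L)]
          if (paste(cod, collapse = "") %in% c(STOP_CODONS, "ATG")) {
            down[cs:(cs + 2L)] <- defuse_codon(cod)
          }
        }
        utr_chars[(p - 9L):p] <- strsplit(ctx$upstream, "")[[1]]
        utr_chars[(p + 1L):(p + 3L)] <- strsplit(spec$planted_tic_codons[j],
                                                 "")[[1]]
        utr_chars[(p + 4L):(p + 13L)] <- down
        # codons 5 and 6 (0-based starts p+12, p+15) extend past the flank
        for (cs in c(p + 12L, p + 15L)) {
          cod <- utr_chars[(cs + 1L):(cs + 3L)]
          if (paste(cod, collapse = "") %in% STOP_CODONS) {
            utr_chars[(cs + 1L):(cs + 3L)] <- defuse_codon(cod)
          }
        }
      }
    }

    body_n <- (cds_lens[i] - 6L) %/% 3L
    cds_chars <- c("A", "T", "G",
                   unlist(strsplit(sample(NONSTOP_CODONS, body_n,
                                          replace = TRUE), "")),
                   strsplit(sample(STOP_CODONS, 1L), "")[[1]])
    # main TIC downstream flank = first 10 nt after the ATG
    cds_chars[4:13] <- strsplit(main_ctx$downstream[i], "")[[1]]
    for (ci in 2:5) {                     # keep the CDS frame open
      idx <- (3L * ci - 2L):(3L * ci)
      cod <- cds_chars[idx]
      if (paste(cod, collapse = "") %in% STOP_CODONS) {
        cds_chars[idx] <- defuse_codon(cod)
      }
    }

    utr3_chars <- if (spec$utr3_length > 0L) {
      sample(BASES, spec$utr3_length, replace = TRUE, prob = comp)
    } else character(0)

    id <- sprintf("synth_%04d", i)
    transcripts[[i]] <- transcript_record(
      id = id,
      sequence = paste(c(utr_chars, cds_chars, utr3_chars), collapse = ""),
      main_tic_start = utr,
      cds_end = utr + cds_lens[i])
    truth[[i]] <- if (k > 0L) {
      data.frame(transcript_id = id, position = slots,
                 codon = spec$planted_tic_codons,
                 concentration = spec$context_concentration,
                 main_tic_start = utr, stringsAsFactors = FALSE)
    } else NULL
  }
  names(transcripts) <- vapply(transcripts, function(t) t$id, character(1))
  truth_df <- if (k > 0L) do.call(rbind, truth) else
    data.frame(transcript_id = character(0), position = integer(0),
               codon = character(0), concentration = numeric(0),
               main_tic_start = integer(0), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  list(transcripts = transcripts, truth = truth_df, spec = spec)
}

#' Emit peptide evidence for a cohort's planted TICs
#'
#' For each planted TIC, translates the downstream codons and emits either an
#' intact N-terminal peptide (initiator Met followed by the downstream
#' residues) or, with probability `cleave_met_fraction`, the
#' methionine-excised acetylated form. Optional decoy peptides violate the
#' upstream-codon rule (no leading M, preceding in-frame codon neither ATG
#' nor near-cognate), so [apply_filters()] must exclude them.
#'
#' @param truth the `truth` data frame of [generate_cohort()] (or the cohort
#'   list itself).
#' @param transcripts the cohort's transcript list (ignored when `truth` is
#'   a cohort list).
#' @param cleave_met_fraction probability that a peptide loses its initiator
#'   Met.
#' @param peptide_length target peptide length in residues.
#' @param n_decoys number of decoy evidences to inject.
#' @param seed optional integer seed.
#' @return a data frame with columns `peptide`, `transcript_id`,
#'   `acetylated`, `source`, `tic_position` (0-based planted position, NA
#'   for decoys).
#' @export
generate_peptide_evidence <- function(truth, transcripts = NULL,
                                      cleave_met_fraction = 0.5,
                                      peptide_length = 8L,
                                      n_decoys = 0L, seed = NULL) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth)) {
    transcripts <- truth$transcripts
    truth <- truth$truth
  }
  stopifnot(is.data.frame(truth), is.list(transcripts),
            cleave_met_fraction >= 0, cleave_met_fraction <= 1,
            peptide_length >= 5L)
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- transcripts[[truth$transcript_id[i]]]
    p <- truth$position[i]
    n_aa <- min(peptide_length - 1L,
                (nchar(tr$sequence) - (p + 3L)) %/% 3L)
    starts <- p + 3L + 3L * (seq_len(n_aa) - 1L) + 1L
    aa <- unname(code[substring(tr$sequence, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"
    stop_at <- match("*", aa)
    if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
    tail_pep <- paste(aa, collapse = "")
    if (nchar(tail_pep) < 5L) next   # no usable peptide (should not happen)
    cleave <- stats::runif(1) < cleave_met_fraction &&
      !startsWith(tail_pep, "M")
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = if (cleave) tail_pep else paste0("M", tail_pep),
      transcript_id = tr$id,
      acetylated = cleave,
      source = "synthetic",
      tic_position = p,
      stringsAsFactors = FALSE)
  }
  if (n_decoys > 0L && length(transcripts)) {
    ok_codons <- c("ATG", near_cognate_set())
    for (d in seq_len(n_decoys)) {
      placed <- FALSE
      for (attempt in 1:200) {
        tr <- transcripts[[sample(length(transcripts), 1L)]]
        len <- nchar(tr$sequence)
        if (len < 40L) next
        q <- sample(3:(len - 21L), 1L)
        prev <- substr(tr$sequence, q - 2L, q)
        if (prev %in% ok_codons) next
        starts <- q + 3L * (0:5) + 1L
        aa <- unname(code[substring(tr$sequence, starts, starts + 2L)])
        if (anyNA(aa) || any(aa == "*") || aa[1] == "M") next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = paste(aa, collapse = ""),
          transcript_id = tr$id, acetylated = TRUE,
          source = "synthetic-decoy", tic_position = NA_integer_,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place a decoy peptide")
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), transcript_id = character(0),
                      acetylated = logical(0), source = character(0),
                      tic_position = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
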