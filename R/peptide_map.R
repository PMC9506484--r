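# Inference of TICs from N-terminal peptide evidence, with the
# methionine-excision exclusion rules and product classification.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Translate the three forward reading frames
#'
#' Standard genetic code, stop codons rendered `*`, trailing partial codons
#' dropped. Inputs are mRNA-sense transcripts, so only the three forward
#' frames are biologically meaningful and only those are returned.
#'
#' @param sequence nucleotide string, length >= 3.
#' @param lenient if `TRUE`, codons containing characters outside A/C/G/T
#'   translate to `X` instead of raising an error.
#' @return a character vector of 3 amino-acid strings (frame offsets 0, 1, 2;
#'   a frame too short for a single codon gives `""`).
#' @export
translate_frames <- function(sequence, lenient = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) stop("sequence must be at least 3 nt long")
  code <- Biostrings::GENETIC_CODE
  vapply(0:2, function(f) {
    n_codon <- (nchar(sequence) - f) %/% 3L
    if (n_codon < 1L) return("")
    starts <- f + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(sequence, starts, starts + 2L)
    aa <- unname(code[codons])
    if (anyNA(aa)) {
      if (!lenient) {
        stop("sequence contains a codon outside the A/C/G/T alphabet: ",
             codons[which(is.na(aa))[1]])
      }
      aa[is.na(aa)] <- "X"
    }
    paste(aa, collapse = "")
  }, character(1))
}

#' Construct a piece of N-terminal peptide evidence
#'
#' @param peptide amino-acid string (single-letter codes), length >= 5 by
#'   default — shorter matches are unreliable.
#' @param transcript_id identifier of the transcript the peptide belongs to.
#' @param acetylated whether the peptide N-terminus was acetylated (evidence
#'   that it is a true protein N-terminus, possibly after initiator-Met
#'   excision).
#' @param source free-text provenance (e.g. "mass spec").
#' @param min_length minimum accepted peptide length.
#' @return an object of class `peptide_evidence`.
#' @export
peptide_evidence <- function(peptide, transcript_id, acetylated = FALSE,
                             source = "", min_length = 5L) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  peptide <- toupper(peptide)
  if (nchar(peptide) < min_length) {
    stop(sprintf("peptide %s is shorter than the minimum length %d",
                 peptide, min_length))
  }
  bad <- setdiff(strsplit(peptide, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop("peptide contains characters outside the 20-letter alphabet: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(peptide = peptide, transcript_id = transcript_id,
                 acetylated = isTRUE(acetylated), source = source),
            class = "peptide_evidence")
}

#' Map a peptide onto a transcript's forward-frame translations
#'
#' Non-methionine-initial peptides must match a forward-frame translation
#' exactly. For peptides starting with M the match is initiator-aware: the
#' initiator methionine is delivered by the initiator tRNA whatever the
#' codon, so residues 2..k are matched exactly and the reported position is
#' the codon aligned with the initial M (which need not translate to M — it
#' may be a near-cognate codon; [infer_tic()] checks it).
#'
#' @param evidence a [peptide_evidence()] or a plain peptide string.
#' @param transcript a [transcript_record()].
#' @return an ascending integer vector of 0-based nucleotide positions of the
#'   first matched codon; empty if the peptide does not map (the caller then
#'   discards the evidence).
#' @export
map_peptide <- function(evidence, transcript) {
  stopifnot(inherits(transcript, "transcript_record"))
  peptide <- if (inherits(evidence, "peptide_evidence")) evidence$peptide
             else toupper(evidence)
  frames <- translate_frames(transcript$sequence, lenient = TRUE)
  m_initial <- startsWith(peptide, "M")
  pattern <- if (m_initial) substr(peptide, 2L, nchar(peptide)) else peptide
  if (!nzchar(pattern)) return(integer(0))
  hits <- integer(0)
  for (f in 0:2) {
    if (!nzchar(frames[f + 1L])) next
    g <- gregexpr(pattern, frames[f + 1L], fixed = TRUE)[[1]]
    if (g[1] == -1L) next
    # aa index a (1-based) in frame f starts at nucleotide f + 3*(a-1)
    nt <- f + 3L * (as.integer(g) - 1L)
    if (m_initial) nt <- nt - 3L   # initiator codon sits one codon 5'
    hits <- c(hits, nt[nt >= 0L])
  }
  sort(unique(hits))
}

new_mapped_tic <- function(transcript_id, position, codon, met_cleaved,
                           status, exclusion_reason = "",
                           product_class = NA_character_) {
  structure(list(transcript_id = transcript_id, position = position,
                 codon = codon, met_cleaved = met_cleaved,
                 product_class = product_class, status = status,
                 exclusion_reason = exclusion_reason),
            class = "mapped_tic")
}

#' Infer the TIC behind a mapped peptide
#'
#' Applies the methionine-excision rules. A peptide with an N-terminal M maps
#' directly onto its initiator codon (`met_cleaved = FALSE`); the codon is
#' still checked to be ATG or near-cognate and the record is excluded with an
#' explanatory reason if not. A peptide without an N-terminal M is assumed to
#' have lost its initiator Met post-translationally, so the codon one step
#' upstream and in frame is taken as the TIC (`met_cleaved = TRUE`); if that
#' codon is neither ATG nor near-cognate, more than the initiator residue was
#' likely cleaved and the evidence is excluded rather than searched further
#' upstream. With `strict_acetyl = TRUE` the cleavage inference is applied to
#' acetylated peptides only; non-acetylated peptides without a leading M are
#' then excluded outright.
#'
#' @param match_position 0-based position from [map_peptide()].
#' @param evidence a [peptide_evidence()].
#' @param transcript a [transcript_record()].
#' @param strict_acetyl restrict Met-cleavage inference to acetylated
#'   peptides.
#' @return a `mapped_tic` object with fields `transcript_id`, `position`,
#'   `codon`, `met_cleaved`, `product_class` (filled by
#'   [classify_product()]), `status` (`"KEPT"`/`"EXCLUDED"`) and
#'   `exclusion_reason`.
#' @export
infer_tic <- function(match_position, evidence, transcript,
                      strict_acetyl = FALSE) {
  stopifnot(inherits(evidence, "peptide_evidence"),
            inherits(transcript, "transcript_record"))
  match_position <- as.integer(match_position)
  ok_codons <- c("ATG", near_cognate_set())
  codon_at <- function(p) substr(transcript$sequence, p + 1L, p + 3L)
  if (startsWith(evidence$peptide, "M")) {
    codon <- codon_at(match_position)
    if (codon %in% ok_codons) {
      new_mapped_tic(transcript$id, match_position, codon,
                     met_cleaved = FALSE, status = "KEPT")
    } else {
      new_mapped_tic(transcript$id, match_position, codon,
                     met_cleaved = FALSE, status = "EXCLUDED",
                     exclusion_reason = "M-initial peptide at non-near-cognate codon")
    }
  } else {
    if (strict_acetyl && !evidence$acetylated) {
      return(new_mapped_tic(transcript$id, match_position,
                            codon_at(match_position), met_cleaved = FALSE,
                            status = "EXCLUDED",
                            exclusion_reason = "non-acetylated peptide without N-terminal methionine"))
    }
    tic_pos <- match_position - 3L
    if (tic_pos < 0L) {
      return(new_mapped_tic(transcript$id, match_position,
                            codon_at(match_position), met_cleaved = TRUE,
                            status = "EXCLUDED",
                            exclusion_reason = "no upstream codon"))
    }
    codon <- codon_at(tic_pos)
    if (codon %in% ok_codons) {
      new_mapped_tic(transcript$id, tic_pos, codon,
                     met_cleaved = TRUE, status = "KEPT")
    } else {
      new_mapped_tic(transcript$id, tic_pos, codon,
                     met_cleaved = TRUE, status = "EXCLUDED",
                     exclusion_reason = "both exclusion conditions met")
    }
  }
}

#' Classify the product initiated at an inferred TIC
#'
#' A TIC upstream of the main TIC that is in frame with the CDS and not
#' separated from it by an in-frame stop initiates an N-terminally extended
#' variant of the main protein (`N_EXTENSION`); out of frame or behind an
#' in-frame stop it initiates a novel upstream product (`NOVEL_UPSTREAM`).
#' TICs at or past the main TIC are `MAIN` or `DOWNSTREAM`.
#'
#' @param tic a KEPT `mapped_tic` from [infer_tic()].
#' @param transcript the matching [transcript_record()].
#' @return one of `"N_EXTENSION"`, `"NOVEL_UPSTREAM"`, `"DOWNSTREAM"`,
#'   `"MAIN"`.
#' @export
classify_product <- function(tic, transcript) {
  stopifnot(inherits(tic, "mapped_tic"), inherits(transcript, "transcript_record"))
  p <- tic$position
  m <- transcript$main_tic_start
  if (p == m) return("MAIN")
  if (p > m) return("DOWNSTREAM")
  if ((m - p) %% 3L != 0L) return("NOVEL_UPSTREAM")
  # in frame: look for an in-frame stop strictly between TIC and main TIC
  if (m - 3L >= p + 3L) {
    between <- seq.int(p + 3L, m - 3L, by = 3L)
    codons <- substring(transcript$sequence, between + 1L, between + 3L)
    if (any(codons %in% STOP_CODONS)) return("NOVEL_UPSTREAM")
  }
  "N_EXTENSION"
}

#' Run the full peptide-evidence pipeline
#'
#' Maps each piece of evidence, infers its TIC, applies the exclusion rules,
#' classifies kept TICs, and deduplicates identical
#' (transcript, position, codon) TICs so the kept table counts unique TICs.
#' Unmapped peptides and excluded inferences land in the `excluded` table
#' with reasons. The output is sorted, hence invariant to input order.
#'
#' @param evidence a data frame with columns `peptide`, `transcript_id`,
#'   `acetylated` (logical), and optionally `source`; or a list of
#'   [peptide_evidence()] objects.
#' @param transcripts a list of [transcript_record()]s (named by id, or
#'   names are taken from the records).
#' @param drop_atg if `TRUE`, kept TICs whose codon is ATG are moved to the
#'   excluded table (to focus on noncanonical TICs).
#' @param strict_acetyl passed to [infer_tic()].
#' @param min_peptide_length evidence with shorter peptides is excluded.
#' @return a list with data frames `kept` (columns `transcript_id`,
#'   `position`, `codon`, `met_cleaved`, `product_class`, `n_evidence`) and
#'   `excluded` (`transcript_id`, `peptide`, `reason`).
#' @export
apply_filters <- function(evidence, transcripts, drop_atg = FALSE,
                          strict_acetyl = FALSE, min_peptide_length = 5L) {
  if (is.data.frame(evidence)) {
    if (is.null(evidence$source)) evidence$source <- ""
    ev_list <- lapply(seq_len(nrow(evidence)), function(i) {
      list(peptide = toupper(evidence$peptide[i]),
           transcript_id = evidence$transcript_id[i],
           acetylated = isTRUE(as.logical(evidence$acetylated[i])),
           source = evidence$source[i])
    })
  } else {
    ev_list <- evidence
  }
  if (is.null(names(transcripts)) || !all(nzchar(names(transcripts)))) {
    names(transcripts) <- vapply(transcripts, function(t) t$id, character(1))
  }
  kept <- list(); excluded <- list()
  push_excluded <- function(tid, pep, reason) {
    excluded[[length(excluded) + 1L]] <<- data.frame(
      transcript_id = tid, peptide = pep, reason = reason,
      stringsAsFactors = FALSE)
  }
  for (ev_raw in ev_list) {
    pep <- ev_raw$peptide; tid <- ev_raw$transcript_id
    ev <- tryCatch(
      peptide_evidence(pep, tid, ev_raw$acetylated, ev_raw$source,
                       min_length = min_peptide_length),
      error = function(e) e)
    if (inherits(ev, "error")) {
      push_excluded(tid, pep, paste("invalid peptide:", conditionMessage(ev)))
      next
    }
    tr <- transcripts[[tid]]
    if (is.null(tr)) {
      push_excluded(tid, pep, "transcript not found")
      next
    }
    matches <- map_peptide(ev, tr)
    if (!length(matches)) {
      push_excluded(tid, pep, "unmapped")
      next
    }
    for (mp in matches) {
      tic <- infer_tic(mp, ev, tr, strict_acetyl = strict_acetyl)
      if (tic$status == "KEPT") {
        tic$product_class <- classify_product(tic, tr)
        kept[[length(kept) + 1L]] <- data.frame(
          transcript_id = tic$transcript_id, position = tic$position,
          codon = tic$codon, met_cleaved = tic$met_cleaved,
          product_class = tic$product_class, stringsAsFactors = FALSE)
      } else {
        push_excluded(tid, pep, tic$exclusion_reason)
      }
    }
  }
  kept_df <- if (length(kept)) do.call(rbind, kept) else
    data.frame(transcript_id = character(0), position = integer(0),
               codon = character(0), met_cleaved = logical(0),
               product_class = character(0), stringsAsFactors = FALSE)
  excl_df <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(transcript_id = character(0), peptide = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  if (nrow(kept_df)) {
    key <- paste(kept_df$transcript_id, kept_df$position, kept_df$codon)
    kept_df$n_evidence <- as.integer(table(key)[key])
    kept_df <- kept_df[!duplicated(key), , drop = FALSE]
    if (drop_atg) {
      is_atg <- kept_df$codon == "ATG"
      if (any(is_atg)) {
        excl_df <- rbind(excl_df, data.frame(
          transcript_id = kept_df$transcript_id[is_atg],
          peptide = NA_character_,
          reason = "ATG TIC excluded by flag", stringsAsFactors = FALSE))
        kept_df <- kept_df[!is_atg, , drop = FALSE]
      }
    }
    kept_df <- kept_df[order(kept_df$transcript_id, kept_df$position), ,
                       drop = FALSE]
    rownames(kept_df) <- NULL
  } else {
    kept_df$n_evidence <- integer(0)
  }
  if (nrow(excl_df)) {
    excl_df <- excl_df[order(excl_df$transcript_id, excl_df$peptide,
                             excl_df$reason), , drop = FALSE]
    rownames(excl_df) <- NULL
  }
  list(kept = kept_df, excluded = excl_df)
}
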