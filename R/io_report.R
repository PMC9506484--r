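# File I/O for transcripts and reports, the colour-binned annotation view,
# and the command-line interface.

KSS_COLORS <- c("blue", "teal", "green", "orange", "red")

tsv_header_comment <- function(matrix = NULL, params = NULL) {
  bits <- c(sprintf("# kozakscan %s",
                    as.character(utils::packageVersion("kozakscan"))),
            if (!is.null(matrix)) sprintf("# matrix: %s", matrix$source_label),
            if (!is.null(params) && length(params))
              sprintf("# params: %s",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = "; ")))
  paste(bits, collapse = "\n")
}

write_report_tsv <- function(df, path, matrix = NULL, params = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tsv_header_comment(matrix, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Candidate/rank tables carry 0-based positions internally; reports are
# 1-based.
with_position_1based <- function(df) {
  if (nrow(df) == 0 && !"position" %in% names(df)) return(df)
  df$position_1based <- df$position + 1L
  df[, c(setdiff(names(df), c("position", "position_1based"))[1],
         "position_1based",
         setdiff(names(df), c("position", "position_1based"))[-1]),
     drop = FALSE]
}

#' Read transcripts from FASTA plus a sidecar annotation table
#'
#' The annotation TSV carries 1-based coordinates (columns `transcript_id`,
#' `main_tic_start_1based`, optional `cds_end_1based` — 1-based inclusive CDS
#' end — and optional `gene`); they are converted to the internal 0-based
#' convention. Every annotated id must be present in the FASTA (ids are the
#' first whitespace-separated token of the FASTA header).
#'
#' @param fasta_path path to a FASTA file of mRNA-sense transcripts.
#' @param annotation_path path to the annotation TSV.
#' @return a named list of [transcript_record()]s (annotation order).
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  ann <- utils::read.delim(annotation_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "main_tic_start_1based")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(ann$transcript_id, names(seqs))
  if (length(absent)) {
    stop("annotation references transcript(s) absent from the FASTA: ",
         paste(absent, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(ann)), function(i) {
    id <- ann$transcript_id[i]
    cds_end <- if ("cds_end_1based" %in% names(ann)) ann$cds_end_1based[i] else NA
    gene <- if ("gene" %in% names(ann)) ann$gene[i] else NA_character_
    transcript_record(id = id, sequence = as.character(seqs[[id]]),
                      main_tic_start = ann$main_tic_start_1based[i] - 1L,
                      cds_end = if (is.na(cds_end)) NA else as.integer(cds_end),
                      gene = gene)
  })
  names(out) <- ann$transcript_id
  out
}

#' Read transcripts from a GenBank flat file
#'
#' Minimal parser for GenBank nucleotide records: LOCUS name, the single CDS
#' feature (simple `start..end` locations only; a record with several CDS
#' features is ambiguous and raises an error asking the user to choose), the
#' optional `/gene` qualifier, and the ORIGIN sequence. Produces the same
#' records as the FASTA + annotation route for equivalent content.
#'
#' @param path GenBank flat file (one or more records).
#' @return a named list of [transcript_record()]s.
#' @export
read_transcripts_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- grep("^//\\s*$", lines)
  if (!length(rec_breaks)) stop("no GenBank record terminator (//) found in ", path)
  starts <- c(1L, head(rec_breaks, -1L) + 1L)
  out <- list()
  for (r in seq_along(rec_breaks)) {
    rec <- lines[starts[r]:rec_breaks[r]]
    rec <- rec[nzchar(trimws(rec)) | seq_along(rec) > 0]
    locus <- grep("^LOCUS", rec, value = TRUE)
    if (!length(locus)) next
    id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])), "\\s+")[[1]][1]
    cds_lines <- grep("^\\s{2,}CDS\\s", rec)
    if (!length(cds_lines)) {
      stop(sprintf("GenBank record %s has no CDS feature", id))
    }
    if (length(cds_lines) > 1L) {
      stop(sprintf(
        "GenBank record %s has %d CDS features; extract the one you want into a FASTA + annotation table",
        id, length(cds_lines)))
    }
    loc <- trimws(sub("^\\s+CDS\\s+", "", rec[cds_lines]))
    if (grepl("join|complement", loc)) {
      stop(sprintf("GenBank record %s: only simple start..end CDS locations are supported, got '%s'",
                   id, loc))
    }
    m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("GenBank record %s: cannot parse CDS location '%s'", id, loc))
    }
    cds_start_1b <- as.integer(m[2]); cds_end_1b <- as.integer(m[3])
    gene <- NA_character_
    gq <- grep("/gene=\"", rec, value = TRUE)
    if (length(gq)) gene <- sub('.*?/gene="([^"]+)".*', "\\1", gq[1])
    origin_at <- grep("^ORIGIN", rec)
    if (!length(origin_at)) stop(sprintf("GenBank record %s lacks ORIGIN", id))
    seq_lines <- rec[(origin_at[1] + 1L):(length(rec) - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    sequence <- chartr("U", "T", sequence)
    out[[id]] <- transcript_record(
      id = id, sequence = sequence,
      main_tic_start = cds_start_1b - 1L,
      cds_end = cds_end_1b,   # 1-based inclusive == 0-based exclusive
      gene = gene)
  }
  if (!length(out)) stop("no parsable GenBank records in ", path)
  out
}

#' Write transcripts as FASTA plus annotation TSV
#'
#' Inverse of [read_transcripts()]: reading the written pair reproduces the
#' records.
#'
#' @param transcripts a (named) list of [transcript_record()]s.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(transcripts, function(t) t$sequence, character(1)))
  names(seqs) <- vapply(transcripts, function(t) t$id, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(
    transcript_id = vapply(transcripts, function(t) t$id, character(1)),
    main_tic_start_1based = vapply(transcripts,
                                   function(t) t$main_tic_start + 1L, integer(1)),
    cds_end_1based = vapply(transcripts, function(t) t$cds_end, integer(1)),
    gene = vapply(transcripts, function(t) t$gene, character(1)),
    stringsAsFactors = FALSE)
  write_report_tsv(ann, annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in exactly the formats the scanners read back: FASTA,
#' annotation TSV, ground-truth TSV (1-based positions).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return a named character vector of the three paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  ann <- file.path(dir, paste0(prefix, "_annotation.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_transcripts(cohort$transcripts, fasta, ann)
  tdf <- cohort$truth
  tdf$position_1based <- tdf$position + 1L
  write_report_tsv(tdf[, c("transcript_id", "position_1based", "codon",
                           "concentration", "main_tic_start")], truth)
  c(fasta = fasta, annotation = ann, truth = truth)
}

#' Colour-binned candidate annotation of a transcript
#'
#' Highlights every fully flanked candidate codon with its KSS (3 decimals)
#' and a colour bin from blue (lowest scores) through teal, green and orange
#' to red (highest), so that higher-scoring codons never receive a lower
#' bin. Overlapping candidates are resolved greedily 5' to 3': a candidate
#' overlapping an already highlighted one is reported in the table but not
#' rendered inline.
#'
#' @param transcript a [transcript_record()].
#' @param matrix a [bits_matrix()].
#' @param codon_filter candidate codons (default ATG + near-cognate).
#' @param bin_edges four ascending KSS thresholds splitting \[0, 1\] into the
#'   five colour bins.
#' @param region region to scan, as in [enumerate_candidates()].
#' @return an object of class `tic_annotation` with the transcript, the
#'   candidate table (`position`, `codon`, `kss`, `bin`, `color`,
#'   `rendered`), and the bin edges. Render with
#'   [render_annotation_text()] / [render_annotation_html()].
#' @export
annotate_transcript <- function(transcript, matrix,
                                codon_filter = c("ATG", near_cognate_set()),
                                bin_edges = c(0.50, 0.62, 0.72, 0.80),
                                region = "FULL") {
  stopifnot(length(bin_edges) == 4L, !is.unsorted(bin_edges, strictly = TRUE))
  cands <- enumerate_candidates(transcript, region = region,
                                codon_filter = codon_filter, matrix = matrix)
  cands <- cands[cands$has_full_flanks, , drop = FALSE]
  if (nrow(cands)) {
    cands$bin <- findInterval(cands$kss, bin_edges) + 1L
    cands$color <- KSS_COLORS[cands$bin]
    cands$rendered <- TRUE
    last_end <- -1L
    for (i in seq_len(nrow(cands))) {
      if (cands$position[i] < last_end) {
        cands$rendered[i] <- FALSE
      } else {
        last_end <- cands$position[i] + 3L
      }
    }
  } else {
    cands$bin <- integer(0); cands$color <- character(0)
    cands$rendered <- logical(0)
  }
  rownames(cands) <- NULL
  structure(list(transcript_id = transcript$id,
                 sequence = transcript$sequence,
                 candidates = cands, bin_edges = bin_edges),
            class = "tic_annotation")
}

#' @export
print.tic_annotation <- function(x, ...) {
  cat(sprintf("<tic_annotation> %s: %d candidate(s), bins at %s\n",
              x$transcript_id, nrow(x$candidates),
              paste(x$bin_edges, collapse = "/")))
  invisible(x)
}

#' Plain-text rendering of an annotation report
#'
#' Each rendered candidate codon appears as `[COD(0.123;color)]` in place of
#' its three nucleotides; [strip_annotation_markup()] inverts the rendering
#' back to the exact input sequence.
#'
#' @param annotation a [annotate_transcript()] result.
#' @return a single string.
#' @export
render_annotation_text <- function(annotation) {
  s <- annotation$sequence
  cands <- annotation$candidates[annotation$candidates$rendered, , drop = FALSE]
  if (!nrow(cands)) return(s)
  pieces <- character(0)
  cursor <- 0L   # 0-based, next unwritten position
  for (i in seq_len(nrow(cands))) {
    p <- cands$position[i]
    pieces <- c(pieces,
                substr(s, cursor + 1L, p),
                sprintf("[%s(%.3f;%s)]", cands$codon[i], cands$kss[i],
                        cands$color[i]))
    cursor <- p + 3L
  }
  paste0(paste(pieces, collapse = ""), substr(s, cursor + 1L, nchar(s)))
}

#' Strip annotation markup back to the bare sequence
#'
#' @param text output of [render_annotation_text()].
#' @return the unannotated nucleotide sequence.
#' @export
strip_annotation_markup <- function(text) {
  gsub("\\[([ACGTN]{3})\\([0-9]\\.[0-9]{3};[a-z]+\\)\\]", "\\1", text)
}

#' Static HTML rendering of an annotation report
#'
#' Self-contained HTML (no external assets) with candidates as coloured
#' spans, KSS in parentheses after each codon.
#'
#' @inheritParams render_annotation_text
#' @return a single HTML string.
#' @export
render_annotation_html <- function(annotation) {
  s <- annotation$sequence
  cands <- annotation$candidates[annotation$candidates$rendered, , drop = FALSE]
  css <- c(blue = "#2c4fd8", teal = "#0f9b8e", green = "#2f9e2f",
           orange = "#e08a00", red = "#d42020")
  pieces <- character(0)
  cursor <- 0L
  if (nrow(cands)) {
    for (i in seq_len(nrow(cands))) {
      p <- cands$position[i]
      pieces <- c(pieces, substr(s, cursor + 1L, p),
                  sprintf(
                    '<span style="color:%s;font-weight:bold" title="position %d">%s</span><sub>(%.3f)</sub>',
                    css[[cands$color[i]]], p + 1L, cands$codon[i], cands$kss[i]))
      cursor <- p + 3L
    }
  }
  body <- paste0(paste(pieces, collapse = ""),
                 substr(s, cursor + 1L, nchar(s)))
  paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\"><title>",
         annotation$transcript_id,
         "</title></head><body><h2>", annotation$transcript_id,
         "</h2><p style=\"font-family:monospace;word-wrap:break-word\">",
         body, "</p></body></html>")
}

#' Write a candidate or rank table as a report TSV
#'
#' Emits 1-based positions and a commented header recording the tool
#' version, matrix provenance and parameters.
#'
#' @param df a candidate/rank data frame with a 0-based `position` column.
#' @param path output path.
#' @param matrix optional [bits_matrix()] whose provenance is recorded.
#' @param params optional named list recorded in the header.
#' @return invisibly, the path.
#' @export
write_candidates <- function(df, path, matrix = NULL, params = NULL) {
  out <- df
  if ("position" %in% names(out)) {
    out$position_1based <- out$position + 1L
    out$position <- NULL
    first <- intersect(c("transcript_id", "position_1based"), names(out))
    out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  }
  write_report_tsv(out, path, matrix = matrix, params = params)
}

#' Write a Mann-Whitney comparison result as JSON
#'
#' @param comparison an `mw_comparison`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_comparison <- function(comparison, path) {
  jsonlite::write_json(
    list(group_names = comparison$group_names,
         n = comparison$n,
         medians = comparison$medians,
         u_statistic = comparison$u_statistic,
         p_value_one_sided = comparison$p_value_one_sided,
         alternative = comparison$alternative,
         outlier_removed = comparison$outlier_removed,
         method = comparison$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
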