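# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written as naive loops / enumerations, separate
# from the package's vectorised code paths.

NT <- c("A", "C", "G", "T")

# Brute-force accumulation of the similarity score: walk the 20 flank
# positions one by one with named lookups.
oracle_kss <- function(up, down, m) {
  chars <- c(strsplit(up, "")[[1]], strsplit(down, "")[[1]])
  s <- 0
  mx <- 0
  for (p in 1:20) {
    s <- s + m$heights[p, chars[p]]
    mx <- mx + max(m$heights[p, ])
  }
  s / mx
}

# Exhaustive 3-mer scan.
oracle_scan <- function(sequence, filter) {
  hits <- integer(0); cods <- character(0)
  for (i in 0:(nchar(sequence) - 3L)) {
    cod <- substr(sequence, i + 1L, i + 3L)
    if (cod %in% filter) {
      hits <- c(hits, i); cods <- c(cods, cod)
    }
  }
  data.frame(position = hits, codon = cods, stringsAsFactors = FALSE)
}

# Exact one-sided Mann-Whitney p by full enumeration of group labelings.
oracle_mw_exact_p <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  all_v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  u_obs <- u_of(x, y)
  us <- apply(idx, 2L, function(ii) u_of(all_v[ii], all_v[-ii]))
  mean(us >= u_obs - 1e-9)
}

# Normal approximation with midrank tie correction and continuity
# correction, written from the textbook formula.
oracle_mw_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  z <- (u - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

rand_matrix <- function() {
  bits_matrix(matrix(stats::runif(80, min = 0.01, max = 1), 20, 4,
                     dimnames = list(1:20, NT)),
              source_label = "random test matrix")
}

rand_flank <- function() paste(sample(NT, 10, replace = TRUE), collapse = "")

rand_seq <- function(len) paste(sample(NT, len, replace = TRUE), collapse = "")

rand_transcript <- function(len = NULL, id = "t") {
  if (is.null(len)) len <- sample(50:500, 1)
  transcript_record(id, rand_seq(len),
                    main_tic_start = sample(0:(len - 3L), 1))
}

# Matrix with height(A) = 1 everywhere, 0 otherwise: KSS = fraction of A's
# in the flanks; handy for constructing pools with prescribed scores.
toy_a_matrix <- function() {
  h <- matrix(0, 20, 4, dimnames = list(1:20, NT))
  h[, "A"] <- 1
  bits_matrix(h, "toy all-A matrix")
}

# Flank with exactly k A's (rest C), for prescribed toy-matrix scores.
flank_with_a <- function(k) {
  paste(c(rep("A", k), rep("C", 10 - k)), collapse = "")
}

# Hand-traced peptide-evidence fixture exercising every filter branch.
# Layout (0-based):
#   12  ATG GGA TTA TCA GAT AAA   encodes MGLSDK       (E1, M-initial, ATG)
#   60  ATG                       annotated main TIC
#   90  CTG GGA TTA TCA GAT GAA   encodes (M)GLSDE     (E2/E5, Met-cleaved)
#  120  AAA ACA CCA AAT CAA GTA   TPNQV after AAA      (E3, excluded)
#  150  GTG GCA CGT AAT GAT TGT   encodes (M)ARNDC     (E6, M-initial, GTG)
peptide_fixture <- function() {
  parts <- c(
    "CCTCCTCCTCCT",                    #   0-11
    "ATGGGATTATCAGATAAA",              #  12-29
    strrep("GCA", 10),                 #  30-59
    "ATG",                             #  60-62  main TIC
    strrep("GCA", 9),                  #  63-89
    "CTGGGATTATCAGATGAA",              #  90-107
    strrep("GCA", 4),                  # 108-119
    "AAAACACCAAATCAAGTA",              # 120-137
    strrep("GCA", 4),                  # 138-149
    "GTGGCACGTAATGATTGT",              # 150-167
    "CCTCCTCCTCCT")                    # 168-179
  tr <- transcript_record("fixt", paste(parts, collapse = ""),
                          main_tic_start = 60L)
  evidence <- data.frame(
    peptide = c("MGLSDK", "GLSDE", "TPNQV", "WWWWW", "GLSDE", "MARNDC"),
    transcript_id = "fixt",
    acetylated = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    source = "fixture",
    stringsAsFactors = FALSE)
  list(transcript = tr, evidence = evidence)
}
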