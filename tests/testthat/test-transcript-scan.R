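test_that("near-cognate codons are exactly the Hamming-distance-1 neighbours of ATG", {
  nc <- near_cognate_set()
  expect_length(nc, 9)
  expect_setequal(nc, c("CTG", "GTG", "TTG", "AAG", "ACG", "AGG",
                        "ATA", "ATC", "ATT"))
  expect_false("ATG" %in% nc)
  expect_false("AAA" %in% nc)
  expect_true("CTG" %in% nc)

  common <- common_near_cognate_set()
  expect_length(common, 4)
  expect_true(all(common %in% nc))
  expect_false("AAG" %in% common)
})

test_that("transcript_record validates its annotation", {
  expect_error(transcript_record("t", "ACGTACGT", 6), "main_tic_start")
  expect_error(transcript_record("t", "ACGTACGTZZ", 0), "outside A/C/G/T")
  expect_error(transcript_record("t", strrep("A", 30), 3, cds_end = 10),
               "multiple of 3")
  tr <- transcript_record("t", strrep("A", 30), 3, cds_end = 12)
  expect_identical(tr$cds_end, 12L)
  # main codon recorded as-is, not forced to ATG
  tr2 <- transcript_record("t", strrep("C", 30), 5)
  expect_identical(substr(tr2$sequence, 6, 8), "CCC")
})

test_that("extract_context slices flanks and enforces their availability", {
  tr <- transcript_record("t", strrep("A", 23), 10)
  ctx <- extract_context(tr, 10)
  expect_identical(ctx$upstream, strrep("A", 10))
  expect_identical(ctx$codon, "AAA")
  expect_identical(ctx$downstream, strrep("A", 10))
  expect_error(extract_context(tr, 9), class = "insufficient_flank")
  expect_error(extract_context(tr, 11), class = "insufficient_flank")

  s <- paste0(strrep("C", 12), "ATG", strrep("G", 15))
  tr <- transcript_record("t", s, 12)
  ctx <- extract_context(tr, 12)
  expect_identical(ctx$upstream, substr(s, 3, 12))
  expect_identical(ctx$codon, substr(s, 13, 15))
  expect_identical(ctx$downstream, substr(s, 16, 25))
})

test_that("enumerate_candidates finds single planted codons in the right regions", {
  tr <- transcript_record("t", paste0(strrep("C", 10), "ATG", strrep("C", 10)), 10)
  got <- enumerate_candidates(tr, region = "FULL", codon_filter = "ATG")
  expect_equal(got$position, 10L)
  expect_identical(got$codon, "ATG")
  expect_identical(got$region, "CDS")

  s <- paste0(strrep("C", 15), "CTG", strrep("C", 22), "ATG", strrep("C", 20))
  tr <- transcript_record("t", s, 40)
  up <- enumerate_candidates(tr, region = "UPSTREAM")
  expect_equal(up$position, 15L)
  expect_identical(up$codon, "CTG")
  full <- enumerate_candidates(tr, region = "FULL")
  expect_setequal(full$position, c(15L, 40L))
})

test_that("a candidate overlapping the main TIC boundary is upstream, but not UTR5", {
  # CTG starting 1 nt before the main TIC
  s <- paste0(strrep("A", 19), "CTGCC", strrep("A", 20))
  tr <- transcript_record("t", s, 20)
  up <- enumerate_candidates(tr, region = "UPSTREAM", codon_filter = "CTG")
  expect_equal(up$position, 19L)
  u5 <- enumerate_candidates(tr, region = "UTR5", codon_filter = "CTG")
  expect_equal(nrow(u5), 0L)
})

test_that("enumeration equals the exhaustive 3-mer oracle and flags partial flanks", {
  set.seed(52)
  filt <- c("ATG", near_cognate_set())
  for (i in 1:20) {
    tr <- rand_transcript(len = sample(50:2000, 1))
    got <- enumerate_candidates(tr, region = "FULL", codon_filter = filt)
    want <- oracle_scan(tr$sequence, filt)
    expect_identical(got$position, want$position)
    expect_identical(got$codon, want$codon)
    # codon round-trips against the sequence slice
    expect_identical(got$codon,
                     substring(tr$sequence, got$position + 1, got$position + 3))
    expect_identical(got$has_full_flanks,
                     got$position >= 10 & got$position + 13 <= nchar(tr$sequence))
  }
})

test_that("region labels partition FULL into disjoint UTR5/CDS/UTR3", {
  set.seed(62)
  for (i in 1:10) {
    len <- sample(100:500, 1)
    main <- sample(10:(len - 40), 1)
    n_codons <- sample(3:floor((len - main - 3) / 3), 1)
    tr <- transcript_record("t", rand_seq(len), main,
                            cds_end = main + 3 * n_codons)
    full <- enumerate_candidates(tr, region = "FULL")
    expect_true(all(full$region[full$position < main] == "UTR5"))
    expect_true(all(full$region[full$position >= tr$cds_end] == "UTR3"))
    expect_true(all(full$region[full$position >= main &
                                full$position < tr$cds_end] == "CDS"))
  }
})

test_that("UPSTREAM on a transcript starting at its main TIC is empty, not an error", {
  tr <- transcript_record("t", paste0("ATG", strrep("C", 27)), 0)
  expect_equal(nrow(enumerate_candidates(tr, region = "UPSTREAM")), 0L)
})

test_that("utr5_length is the 0-based main TIC start", {
  tr <- transcript_record("t", rand_seq(300), 205)
  expect_identical(utr5_length(tr), 205L)
  expect_identical(utr5_length(transcript_record("t", "ATGCCC", 0)), 0L)
})

test_that("padded scoring scores partial-flank candidates with zero-bit padding", {
  m <- toy_a_matrix()
  tr <- transcript_record("t", paste0("ATG", strrep("A", 27)), 0)
  got <- enumerate_candidates(tr, region = "FULL", codon_filter = "ATG",
                              matrix = m, pad = TRUE)
  # no upstream flank at all: only the 10 downstream A's contribute
  expect_equal(got$kss[got$position == 0], 0.5)
  expect_false(got$has_full_flanks[got$position == 0])
  unpadded <- enumerate_candidates(tr, region = "FULL", codon_filter = "ATG",
                                   matrix = m)
  expect_true(is.na(unpadded$kss[unpadded$position == 0]))
})
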