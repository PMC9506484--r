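test_that("translate_frames applies the standard code in the three forward frames", {
  expect_identical(translate_frames("ATGGCC")[1], "MA")
  expect_identical(translate_frames("TATGGCC")[2], "MA")
  expect_identical(translate_frames("ATGTAAGCC")[1], "M*A")
  # trailing partial codons are dropped
  expect_identical(translate_frames("ATGGC")[1], "M")
  expect_error(translate_frames("ATGNCC"), "outside the A/C/G/T")
  expect_identical(translate_frames("ATGNCC", lenient = TRUE)[1], "MX")
})

test_that("translate_frames agrees with an independent codon-table oracle", {
  set.seed(91)
  for (i in 1:10) {
    s <- rand_seq(300)
    got <- translate_frames(s)
    for (f in 0:2) {
      want <- paste(seqinr::translate(strsplit(s, "")[[1]], frame = f),
                    collapse = "")
      expect_identical(got[f + 1], want)
    }
  }
})

test_that("map_peptide finds engineered peptides and returns all loci ascending", {
  # MSTEL encoded once, starting at nucleotide 30
  enc <- "ATGAGCACCGAGTTA"                       # M S T E L
  s <- paste0(strrep("C", 30), enc, strrep("C", 30))
  tr <- transcript_record("t", s, 0)
  expect_identical(map_peptide("MSTEL", tr), 30L)
  expect_identical(map_peptide("WWWWW", tr), integer(0))

  # same peptide encoded at two loci, different frames
  s2 <- paste0(strrep("C", 12), enc, strrep("C", 13), enc, strrep("C", 12))
  tr2 <- transcript_record("t2", s2, 0)
  expect_identical(map_peptide("MSTEL", tr2), c(12L, 40L))
})

test_that("M-initial peptides align onto near-cognate initiator codons", {
  # CTG initiator followed by codons for S T E L
  s <- paste0(strrep("C", 12), "CTG", "AGCACCGAGTTA", strrep("C", 12))
  tr <- transcript_record("t", s, 0)
  expect_identical(map_peptide("MSTEL", tr), 12L)
  tic <- infer_tic(12L, peptide_evidence("MSTEL", "t"), tr)
  expect_identical(tic$status, "KEPT")
  expect_identical(tic$codon, "CTG")
  expect_false(tic$met_cleaved)
})

test_that("infer_tic applies the Met-cleavage exclusion rules", {
  # GLSDE after a CTG: cleaved inference keeps the CTG
  s <- paste0(strrep("C", 12), "CTG", "GGATTATCAGATGAA", strrep("C", 12))
  tr <- transcript_record("t", s, 0)
  ev <- peptide_evidence("GLSDE", "t", acetylated = TRUE)
  mp <- map_peptide(ev, tr)
  expect_identical(mp, 15L)
  tic <- infer_tic(mp, ev, tr)
  expect_identical(tic$status, "KEPT")
  expect_identical(tic$codon, "CTG")
  expect_true(tic$met_cleaved)

  # same peptide preceded by AAA: both exclusion conditions met
  s2 <- paste0(strrep("C", 12), "AAA", "GGATTATCAGATGAA", strrep("C", 12))
  tr2 <- transcript_record("t", s2, 0)
  tic2 <- infer_tic(map_peptide(ev, tr2), ev, tr2)
  expect_identical(tic2$status, "EXCLUDED")
  expect_match(tic2$exclusion_reason, "both exclusion conditions")

  # match at the very 5' end: no upstream codon to inspect
  s3 <- paste0("GGATTATCAGATGAA", strrep("C", 12))
  tr3 <- transcript_record("t", s3, 0)
  tic3 <- infer_tic(0L, ev, tr3)
  expect_identical(tic3$status, "EXCLUDED")
  expect_match(tic3$exclusion_reason, "no upstream codon")

  # strict-acetyl mode refuses cleavage inference for non-acetylated peptides
  ev_na <- peptide_evidence("GLSDE", "t", acetylated = FALSE)
  tic4 <- infer_tic(15L, ev_na, tr, strict_acetyl = TRUE)
  expect_identical(tic4$status, "EXCLUDED")
  tic5 <- infer_tic(15L, ev_na, tr, strict_acetyl = FALSE)
  expect_identical(tic5$status, "KEPT")
})

test_that("classify_product distinguishes extensions, novel ORFs and downstream TICs", {
  mk_tic <- function(pos, codon) {
    structure(list(transcript_id = "t", position = pos, codon = codon,
                   met_cleaved = FALSE, product_class = NA, status = "KEPT",
                   exclusion_reason = ""), class = "mapped_tic")
  }
  # CTG 9 nt upstream of the main ATG, in frame, no stop between
  s <- paste0(strrep("C", 15), "CTG", "GCAGCA", "ATG", strrep("C", 15))
  tr <- transcript_record("t", s, 24)
  expect_identical(classify_product(mk_tic(15L, "CTG"), tr), "N_EXTENSION")
  # in frame but separated by an in-frame stop
  s2 <- paste0(strrep("C", 15), "CTG", "TAAGCA", "ATG", strrep("C", 15))
  tr2 <- transcript_record("t", s2, 24)
  expect_identical(classify_product(mk_tic(15L, "CTG"), tr2), "NOVEL_UPSTREAM")
  # 10 nt upstream: frame-shifted
  s3 <- paste0(strrep("C", 14), "GTG", strrep("C", 7), "ATG", strrep("C", 15))
  tr3 <- transcript_record("t", s3, 24)
  expect_identical(classify_product(mk_tic(14L, "GTG"), tr3), "NOVEL_UPSTREAM")
  # downstream of the main TIC
  expect_identical(classify_product(mk_tic(54L, "ACG"), tr), "DOWNSTREAM")
  expect_identical(classify_product(mk_tic(24L, "ATG"), tr), "MAIN")
})

test_that("apply_filters reproduces the hand-traced fixture partition", {
  fx <- peptide_fixture()
  res <- apply_filters(fx$evidence, list(fx$transcript))

  expect_equal(nrow(res$kept), 3L)
  expect_identical(res$kept$position, c(12L, 90L, 150L))
  expect_identical(res$kept$codon, c("ATG", "CTG", "GTG"))
  expect_identical(res$kept$met_cleaved, c(FALSE, TRUE, FALSE))
  expect_identical(res$kept$product_class,
                   c("N_EXTENSION", "DOWNSTREAM", "DOWNSTREAM"))
  expect_identical(res$kept$n_evidence, c(1L, 2L, 1L))  # GLSDE deduplicated

  expect_equal(nrow(res$excluded), 2L)
  expect_setequal(res$excluded$reason,
                  c("both exclusion conditions met", "unmapped"))
  expect_identical(res$excluded$peptide[res$excluded$reason == "unmapped"],
                   "WWWWW")

  # every kept codon is ATG or near-cognate
  expect_true(all(res$kept$codon %in% c("ATG", near_cognate_set())))

  # the ATG-drop flag moves the ATG TIC to the exclusions
  res2 <- apply_filters(fx$evidence, list(fx$transcript), drop_atg = TRUE)
  expect_identical(res2$kept$codon, c("CTG", "GTG"))
  expect_true(any(res2$excluded$reason == "ATG TIC excluded by flag"))
})

test_that("apply_filters output is invariant to evidence order", {
  fx <- peptide_fixture()
  res1 <- apply_filters(fx$evidence, list(fx$transcript))
  set.seed(101)
  shuffled <- fx$evidence[sample(nrow(fx$evidence)), , drop = FALSE]
  res2 <- apply_filters(shuffled, list(fx$transcript))
  expect_identical(res1$kept, res2$kept)
  expect_identical(sort(res1$excluded$reason), sort(res2$excluded$reason))
})

test_that("unusable evidence is excluded with explanatory reasons", {
  fx <- peptide_fixture()
  ev <- data.frame(peptide = c("MG", "MGLSDK"),
                   transcript_id = c("fixt", "ghost"),
                   acetylated = FALSE, stringsAsFactors = FALSE)
  res <- apply_filters(ev, list(fx$transcript))
  expect_equal(nrow(res$kept), 0L)
  expect_match(res$excluded$reason[res$excluded$transcript_id == "fixt"],
               "invalid peptide")
  expect_match(res$excluded$reason[res$excluded$transcript_id == "ghost"],
               "transcript not found")
})
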