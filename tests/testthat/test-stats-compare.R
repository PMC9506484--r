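test_that("the exact one-sided Mann-Whitney p matches full enumeration", {
  res <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$u_statistic, 9)
  expect_equal(res$p_value_one_sided, 0.05, tolerance = 1e-12)
  expect_equal(res$p_value_one_sided, oracle_mw_exact_p(c(4, 5, 6), c(1, 2, 3)),
               tolerance = 1e-12)

  set.seed(111)
  for (i in 1:10) {
    x <- round(runif(sample(3:6, 1)), 4)
    y <- round(runif(sample(3:6, 1)), 4)
    res <- mann_whitney_one_sided(x, y)
    expect_equal(res$p_value_one_sided, oracle_mw_exact_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give p >= 0.5 and empty groups error", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  expect_gte(mann_whitney_one_sided(x, x)$p_value_one_sided, 0.5)
  expect_error(mann_whitney_one_sided(numeric(0), x), "non-empty")
})

test_that("U statistics of the two orientations sum to n1*n2, ties included", {
  set.seed(121)
  for (i in 1:20) {
    x <- sample(seq(0, 1, by = 0.05), sample(5:40, 1), replace = TRUE)
    y <- sample(seq(0, 1, by = 0.05), sample(5:40, 1), replace = TRUE)
    u1 <- mann_whitney_one_sided(x, y)$u_statistic
    u2 <- mann_whitney_one_sided(y, x)$u_statistic
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("large-sample p agrees with the hand-derived normal approximation", {
  set.seed(131)
  for (i in 1:10) {
    x <- rnorm(60, mean = 0.1)
    y <- rnorm(55)
    got <- mann_whitney_one_sided(x, y)$p_value_one_sided
    want <- oracle_mw_normal_p(x, y)
    expect_equal(got, want, tolerance = 0.02 * max(want, 1e-12))
  }
  # with heavy ties the tie-corrected variance is used
  x <- sample(1:5, 50, replace = TRUE)
  y <- sample(1:5, 50, replace = TRUE)
  expect_equal(mann_whitney_one_sided(x, y)$p_value_one_sided,
               oracle_mw_normal_p(x, y), tolerance = 1e-10)
})

test_that("exact enumeration and asymptotic p agree closely at n = 8 + 8", {
  set.seed(141)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    p_exact <- mann_whitney_one_sided(x, y)$p_value_one_sided
    p_norm <- oracle_mw_normal_p(x, y)
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("sample_baseline is seed-reproducible and sized per transcript", {
  m <- default_kozak_matrix()
  set.seed(151)
  trs <- lapply(1:25, function(i) rand_transcript(len = 200, id = paste0("b", i)))
  s1 <- sample_baseline(trs, m, per_transcript = 4, seed = 99)
  s2 <- sample_baseline(trs, m, per_transcript = 4, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, 100)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # a transcript too short for any full flank is skipped with a warning
  short <- transcript_record("tiny", strrep("A", 20), 0)
  expect_warning(out <- sample_baseline(list(short), m, seed = 1),
                 "no fully flanked position")
  expect_length(out, 0)
})

test_that("baseline codons on background sequence score below consensus contexts", {
  m <- default_kozak_matrix()
  set.seed(161)
  trs <- lapply(1:25, function(i) rand_transcript(len = 500, id = paste0("b", i)))
  base <- sample_baseline(trs, m, per_transcript = 4, seed = 7)
  ctx <- sample_context(m, concentration = 30, n = 100)
  planted <- kozakscan:::score_flank_pairs(ctx$upstream, ctx$downstream, m)
  expect_lt(median(base), median(planted))
})

test_that("compare_kss_groups honours the outlier-removal flag", {
  nc <- c(0.9, 0.8, 0.05); ca <- c(0.5, 0.55, 0.6)
  r1 <- compare_kss_groups(nc, ca, remove_lowest_noncanonical = TRUE)
  expect_true(r1$outlier_removed)
  expect_equal(r1$n[1], 2L)
  expect_equal(r1$medians[1], median(c(0.9, 0.8)))
  r2 <- compare_kss_groups(nc, ca)
  expect_false(r2$outlier_removed)
  expect_equal(r2$n[1], 3L)
  expect_error(compare_kss_groups(0.5, ca, remove_lowest_noncanonical = TRUE),
               "singleton")
})

test_that("compare_utr_lengths carries medians and detects longer 5'UTRs", {
  mk <- function(n, utr, id) {
    lapply(seq_len(n), function(i)
      transcript_record(paste0(id, i), strrep("A", utr + 30), utr))
  }
  a <- mk(20, 205, "a"); b <- mk(20, 112, "b")
  res <- compare_utr_lengths(a, b)
  expect_equal(res$medians, c(205, 112))
  expect_lt(res$p_value_one_sided, 0.01)
  same <- compare_utr_lengths(a, a)
  expect_gte(same$p_value_one_sided, 0.5)
})

test_that("summarize_positions counts upstream candidates exactly", {
  # 13 ATG/near-cognate codons planted before the TIC of interest
  pieces <- character(0)
  for (i in 1:13) pieces <- c(pieces, "CTG", "CC")
  s <- paste0(paste(pieces, collapse = ""), "ACG", strrep("C", 12), "ATG",
              strrep("C", 15))
  tic_pos <- 13L * 5L
  tr <- transcript_record("t", s, tic_pos + 3L + 12L)
  tics <- data.frame(transcript_id = "t", position = tic_pos,
                     stringsAsFactors = FALSE)
  ps <- summarize_positions(tics, list(tr))
  expect_equal(ps$per_tic$n_upstream_candidates, 13L)
  expect_equal(ps$per_tic$dist_5prime, tic_pos)

  # degenerate: TIC at position 0 has nothing upstream
  tr0 <- transcript_record("z", paste0("ACG", strrep("C", 27)), 10)
  ps0 <- summarize_positions(
    data.frame(transcript_id = "z", position = 0L), list(tr0))
  expect_equal(ps0$per_tic$n_upstream_candidates, 0L)

  # brute-force agreement on random transcripts
  set.seed(171)
  for (i in 1:10) {
    tr <- rand_transcript(len = 400)
    p <- sample(20:380, 1)
    ps <- summarize_positions(
      data.frame(transcript_id = "t", position = p), list(tr))
    want <- sum(oracle_scan(tr$sequence,
                            c("ATG", near_cognate_set()))$position < p)
    expect_equal(ps$per_tic$n_upstream_candidates, want)
  }
})

test_that("summarize_positions reports the first-ATG-is-canonical fraction", {
  # one transcript whose 5'-most ATG is the main TIC, one where it is not
  t1 <- transcript_record("t1", paste0(strrep("C", 20), "ATG", strrep("C", 20)), 20)
  t2 <- transcript_record("t2", paste0(strrep("C", 10), "ATG", strrep("C", 7),
                                       "ATG", strrep("C", 20)), 20)
  ps <- summarize_positions(
    data.frame(transcript_id = character(0), position = integer(0)),
    list(t1, t2))
  expect_equal(ps$fraction_first_atg_canonical, 0.5)
  expect_equal(ps$median_utr5_length, 20)
})
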