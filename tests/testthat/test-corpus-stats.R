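test_that("count_corpus reads frame-0 codons and overlapping bicodons", {
  cc <- count_corpus(c(g1 = "ATGAGTAAGTAA"), label = "L")
  expect_s3_class(cc, "sample_counts")
  expect_equal(unname(cc$bicodon_counts[c("ATGAGT", "AGTAAG", "AAGTAA")]),
               c(1L, 1L, 1L))
  expect_equal(sum(cc$bicodon_counts), 3L)   # AAGTAA kept: stop in A-site only
  expect_equal(unname(cc$codon_counts[c("ATG", "AGT", "AAG", "TAA")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(cc$n_codons_total, 4L)
  expect_equal(cc$n_bicodons_total, 3L)
  expect_equal(unname(cc$aa_pair_totals[c("MS", "SK", "K*")]), c(1L, 1L, 1L))
})

test_that("count_corpus skips invalid codons, stop P-sites and ragged sequences", {
  # N-containing codon: both touching bicodons skipped, clean one kept
  cc <- count_corpus(c(g = "ATGNNNAAGTAA"), label = "L")
  expect_equal(sum(cc$bicodon_counts), 1L)
  expect_equal(unname(cc$bicodon_counts["AAGTAA"]), 1L)
  expect_equal(cc$n_codons_total, 3L)  # NNN not a countable codon
  # internal stop: TAAAAG (stop in P-site) must not be counted
  expect_warning(cc2 <- count_corpus(c(g = "ATGTAAAAGTAA"), label = "L"),
                 "stop codon in P-site")
  # ATG TAA AAG TAA: ATGTAA and AAGTAA kept, TAAAAG (stop P-site) skipped
  expect_equal(unname(cc2$bicodon_counts[c("ATGTAA", "AAGTAA")]), c(1L, 1L))
  expect_equal(sum(cc2$bicodon_counts), 2L)
  # length not a multiple of 3: sequence dropped with a warning
  expect_warning(cc3 <- count_corpus(c(a = "ATGAA", b = "ATGAAGTAA"), "L"),
                 "multiple of 3")
  expect_equal(cc3$n_sequences, 1L)
  # empty corpus: all-zero counts, no error
  cc4 <- count_corpus(character(0), "L")
  expect_equal(cc4$n_codons_total, 0L)
  expect_equal(sum(cc4$bicodon_counts), 0L)
})

test_that("sample_counts totals are internally consistent", {
  corp <- make_test_corpora(n = 50, mean_length = 30, seed = 11)
  cc <- count_corpus(corp$low, "L")
  expect_equal(sum(cc$bicodon_counts), cc$n_bicodons_total)
  expect_equal(sum(cc$codon_counts), cc$n_codons_total)
  expect_equal(sum(cc$aa_totals), cc$n_codons_total)
  # per-pair totals aggregate the family counts
  u <- bicodon_table()
  agg <- tapply(cc$bicodon_counts[u$hexamer], u$aa_pair, sum)
  expect_equal(unname(cc$aa_pair_totals[names(agg)]), unname(as.integer(agg)))
})

test_that("Fisher test matches the hypergeometric enumeration oracle", {
  # spot values first
  res <- fisher_bicodon_test(5, 100, 5, 100)
  expect_equal(res$p_value, 1)
  expect_equal(res$S, 1L)
  res2 <- fisher_bicodon_test(3, 10, 7, 10)
  expect_equal(res2$p_value, oracle_fisher_p(3, 10, 7, 10), tolerance = 1e-12)
  # swapping corpora: same p, opposite sign
  res3 <- fisher_bicodon_test(7, 10, 3, 10)
  expect_equal(res3$p_value, res2$p_value)
  expect_equal(res3$S, -res2$S)
  expect_error(fisher_bicodon_test(1, 0, 1, 5), "undefined")
  # random sample of small tables against the oracle
  set.seed(202)
  for (i in 1:200) {
    nL <- sample(1:25, 1); nH <- sample(1:25, 1)
    oL <- sample(0:nL, 1); oH <- sample(0:nH, 1)
    expect_equal(fisher_bicodon_test(oL, nL, oH, nH)$p_value,
                 oracle_fisher_p(oL, nL, oH, nH), tolerance = 1e-9)
  }
})

test_that("residual scores reproduce a hand evaluation on a tiny corpus", {
  # corpus: ATG AGT AAG *, ATG AGC AAG *, ATG TCT AGT *
  # codon counts: ATG 3, AGT 2, AGC 1, TCT 1, AAG 2, TAA 3; N_tot 12, N_p 9
  # e_ij = f_i f_j * 9 / 144 = f_i f_j / 16; rescaled per family:
  #  MS family: e = (6, 3, 3)/16 for ATGAGT/ATGAGC/ATGTCT, sum* o = 3,
  #    scale 4 -> e_hat = 1.5, 0.75, 0.75 -> chi2 = 1/6, 1/12, 1/12
  #  SK family: e_hat(AGTAAG) = 1, (AGCAAG) = .5, (TCTAAG) = .5
  #    -> chi2 = 0, 0.5, 0.5
  #  SS family: e_hat(TCTAGT) = 0.125 -> chi2 = 6.125
  #  S* family: e_hat(AGTTAA) = 0.5 -> chi2 = 0.5; K*: chi2(AAGTAA) = 0
  cc <- count_corpus(c(a = "ATGAGTAAGTAA", b = "ATGAGCAAGTAA",
                       c = "ATGTCTAGTTAA"), "L")
  rs <- residual_scores(cc)
  expect_equal(unname(rs[c("ATGAGT", "ATGAGC", "ATGTCT")]),
               c(1 / 6, 1 / 12, 1 / 12))
  expect_equal(unname(rs[c("AGTAAG", "AGCAAG", "TCTAAG")]), c(0, 0.5, 0.5))
  expect_equal(unname(rs["TCTAGT"]), 6.125)
  expect_equal(unname(rs[c("AGTTAA", "AAGTAA")]), c(0.5, 0))
  # unobserved family with zero expectation: chi2 = 0, never NA/Inf
  expect_equal(unname(rs["GGGGGG"]), 0)
  expect_false(any(is.na(rs)))
})

test_that("residual scores vanish when counts equal the codon-product expectation", {
  # uniform codon and bicodon counts: o is proportional to e within every
  # family, so the rescaled expectation equals o exactly
  cc <- count_corpus(character(0), "L")
  cc$codon_counts[] <- 10L
  cc$bicodon_counts[] <- 5L
  cc$n_codons_total <- sum(cc$codon_counts)
  cc$n_bicodons_total <- sum(cc$bicodon_counts)
  rs <- residual_scores(cc)
  expect_true(all(rs == 0))
})

test_that("RSBU sums to q per family and pi is antisymmetric and bounded", {
  corp <- make_test_corpora(n = 100, mean_length = 40, seed = 12)
  cL <- count_corpus(corp$low, "L"); cH <- count_corpus(corp$high, "H")
  bs <- pause_propensity(cL, cH)
  u <- bicodon_table()
  q <- tapply(u$q, u$aa_pair, unique)
  for (col in c("rsbu_L", "rsbu_H")) {
    fam_sum <- tapply(bs[[col]], bs$aa_pair, sum)
    present <- !is.na(fam_sum)
    expect_equal(as.numeric(fam_sum[present]), as.numeric(q[present]),
                 tolerance = 1e-12)
  }
  # antisymmetry under corpus swap
  bs_swap <- pause_propensity(cH, cL)
  expect_equal(bs_swap$pi, -bs$pi, tolerance = 1e-12)
  # range: |pi| <= q
  ok <- !is.na(bs$pi)
  expect_true(all(abs(bs$pi[ok]) <= bicodon_table()$q[ok] + 1e-12))
  # sign(pi) agrees with S whenever pi != 0 under the family background
  bs_fam <- pause_propensity(cL, cH, fisher_background = "same_pair")
  nz <- !is.na(bs_fam$pi) & bs_fam$pi != 0 & !is.na(bs_fam$S)
  expect_true(all(sign(bs_fam$pi[nz]) == bs_fam$S[nz]))
  # chi2 bookkeeping
  expect_equal(bs$chi2_total, bs$chi2_L + bs$chi2_H)
})

test_that("identical corpora give pi = 0 and p = 1 everywhere", {
  corp <- make_test_corpora(n = 40, mean_length = 30, seed = 13)
  cc <- count_corpus(corp$low, "L")
  bs <- pause_propensity(cc, cc)
  ok <- !is.na(bs$pi)
  expect_true(any(ok))
  expect_true(all(bs$pi[ok] == 0))
  expect_true(all(bs$p_value == 1))
  expect_true(all(bs$signed_log_p == 0))  # p = 1 -> exactly 0 regardless of S
})

test_that("a fully concentrated family reaches the pi = q boundary", {
  # one bicodon carries all of its family in L and none in H
  seq_L <- c(a = "ATGAGTAAGTAA")  # SK family: AGTAAG only
  seq_H <- c(b = "ATGAGCAAATAA")  # SK family: AGCAAA only
  bs <- pause_propensity(count_corpus(seq_L, "L"), count_corpus(seq_H, "H"))
  row <- bs[bs$hexamer == "AGTAAG", ]
  expect_equal(row$rsbu_L, 12)
  expect_equal(row$rsbu_H, 0)
  expect_equal(row$pi, 12)  # q for the SK family
})

test_that("RSCU is 1 for uniform usage and single-codon amino acids", {
  # uniform-by-construction counts
  cc <- count_corpus(character(0), "X")
  cc$codon_counts[] <- 7L
  cc$n_codons_total <- sum(cc$codon_counts)
  aa <- translate_codon(names(cc$codon_counts))
  cc$aa_totals <- stats::setNames(
    as.integer(tapply(cc$codon_counts, aa, sum)[unique(sort(aa))]),
    unique(sort(aa)))
  cs <- rscu_stats(cc, cc)
  expect_true(all(abs(cs$rscu_L - 1) < 1e-12))
  expect_true(all(cs$diff_rscu == 0))
  # real corpus: M and W always have RSCU exactly 1 when present
  corp <- make_test_corpora(n = 30, mean_length = 30, seed = 14)
  cL <- count_corpus(corp$low, "L")
  cs2 <- rscu_stats(cL, cL)
  mw <- cs2[cs2$codon %in% c("ATG", "TGG"), ]
  expect_true(all(mw$rscu_L == 1))
  # per-corpus mean RSCU over each family is 1 where the amino acid occurs
  fam_mean <- tapply(cs2$rscu_L, cs2$aa, mean)
  expect_true(all(abs(fam_mean[!is.na(fam_mean)] - 1) < 1e-12))
})

test_that("null-calibration: Fisher p-values are not anti-conservative", {
  # corpora drawn from the same generative distribution; the exact test is
  # conservative on discrete counts, so the empirical CDF of p must not
  # exceed the nominal level by more than sampling slack
  corp <- make_test_corpora(n = 400, mean_length = 80, seed = 15)
  bs <- pause_propensity(count_corpus(corp$low, "L"),
                         count_corpus(corp$high, "H"))
  p <- bs$p_value[!is.na(bs$p_value)]
  expect_gt(length(p), 3000)
  expect_lt(mean(p < 0.05), 0.05 + 0.02)
  expect_lt(mean(p < 0.20), 0.20 + 0.03)
})
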