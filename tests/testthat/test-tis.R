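# transcript with a clean candidate layout on a plus-strand single exon:
# 5'UTR = 20 C's (no candidate codons), CDS = ATG GCC ... TAA, 3'UTR C's
clean_tis_ann <- function(n_codons = 20L, utr5 = "CCCCCCCCCCCCCCCCCCCC",
                          mid_codon = "GCC") {
  cds <- paste0("ATG", strrep(mid_codon, n_codons - 2L), "TAA")
  txseq <- paste0(utr5, cds, strrep("C", 20))
  ann <- simple_coding_ann(txseq, nchar(utr5), nchar(cds))
  list(ann = ann, atis_tx = nchar(utr5) + 1L, txlen = nchar(txseq))
}

test_that("candidate enumeration finds AUG and near-cognates only", {
  ann <- simple_coding_ann(paste0("CTGCC", "ATGGCTGGGTAA", "CCCCC"), 5L, 12L)
  cand <- enumerate_tis_candidates(ann, "TX1")
  expect_true(all(c("ATG") %in% cand$codon))
  ctg <- cand[codon == "CTG" & tx_pos == 1L]
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$near_cognate)
  expect_equal(ctg$category, "5UTR")
  atg <- cand[codon == "ATG" & tx_pos == 6L]
  expect_equal(atg$category, "aTIS")
  expect_false(atg$near_cognate)
  # GGG differs from ATG at two positions: never a candidate
  expect_false("GGG" %in% cand$codon)
  # the full candidate codon set
  expect_true(all(cand$codon %in% c("ATG", "CTG", "GTG", "TTG", "AAG",
                                    "ACG", "AGG", "ATA", "ATC", "ATT")))
})

test_that("window accumulation sums +/-1 nt and ignores the rest", {
  cl <- clean_tis_ann()
  prof <- toy_profile(rep("chr1", 3), rep("+", 3), c(49L, 50L, 51L),
                      c(1L, 5L, 2L))
  expect_equal(accumulate_window(prof, cl$ann, "TX1", 50L), 8L)
  expect_equal(accumulate_window(prof, cl$ann, "TX1", 70L), 0L)
  off <- toy_profile("chr1", "+", 52L, 7L)    # first+2: outside the window
  expect_equal(accumulate_window(off, cl$ann, "TX1", 50L), 0L)
})

test_that("R statistic follows (X/N) x 10 with its bounds", {
  expect_equal(compute_R(1, 10), 1.0)
  expect_equal(compute_R(10, 10), 10.0)
  expect_equal(compute_R(0, 10), 0.0)
  expect_true(is.na(compute_R(0, 0)))
})

test_that("an aTIS passing all three rules is called TRUE", {
  cl <- clean_tis_ann()
  a <- cl$atis_tx  # 21
  init <- toy_profile(rep("chr1", 2), rep("+", 2), c(a, a + 20L),
                      c(20L, 80L), condition = "initiating")
  elong <- toy_profile(rep("chr1", 2), rep("+", 2), c(a, a + 30L),
                       c(1L, 999L))
  calls <- call_tis(cl$ann, init, elong, translated = "TX1")
  at <- calls[category == "aTIS"]
  expect_equal(nrow(at), 1L)
  expect_equal(at$X_init, 20L)
  expect_equal(at$N_init, 100L)
  expect_equal(at$R_init, 2.0)
  expect_equal(at$R_elong, 0.01)
  expect_equal(at$status, "TRUE")
  expect_true(at$retained)
})

test_that("aTIS without initiating coverage is NO_DATA on translated transcripts", {
  cl <- clean_tis_ann()
  elong <- toy_profile("chr1", "+", cl$atis_tx + 9L, 50L)
  calls <- call_tis(cl$ann, NULL, elong, translated = "TX1")
  at <- calls[category == "aTIS"]
  expect_equal(at$status, "NO_DATA")
  expect_true(at$retained)
  # not translated and no data: nothing emitted
  none <- call_tis(cl$ann, NULL, elong, translated = character())
  expect_equal(nrow(none), 0L)
})

test_that("aTIS with coverage but failing a rule is FALSE yet kept when translated", {
  cl <- clean_tis_ann()
  a <- cl$atis_tx
  # below the aTIS min count of 5
  init <- toy_profile(rep("chr1", 2), rep("+", 2), c(a, a + 20L),
                      c(3L, 97L), condition = "initiating")
  elong <- toy_profile("chr1", "+", a + 30L, 100L)
  calls <- call_tis(cl$ann, init, elong, translated = "TX1")
  at <- calls[category == "aTIS"]
  expect_equal(at$status, "FALSE")
  expect_true(at$retained)
})

test_that("category thresholds discard weak non-aTIS candidates", {
  # CTG at 5'UTR position 10 with accumulated count 9 < 10
  utr5 <- paste0(strrep("C", 9), "CTG", strrep("C", 8))  # CTG at 10..12
  cl <- clean_tis_ann(utr5 = utr5)
  a <- cl$atis_tx
  init <- toy_profile(rep("chr1", 2), rep("+", 2), c(10L, a),
                      c(9L, 50L), condition = "initiating")
  elong <- toy_profile("chr1", "+", a + 30L, 100L)
  calls <- call_tis(cl$ann, init, elong, translated = "TX1")
  expect_equal(nrow(calls[category == "5UTR"]), 0L)

  # same count at 10 passes when raised to the threshold
  init2 <- toy_profile(rep("chr1", 2), rep("+", 2), c(10L, a),
                       c(10L, 50L), condition = "initiating")
  calls2 <- call_tis(cl$ann, init2, elong, translated = "TX1")
  expect_equal(nrow(calls2[category == "5UTR"]), 1L)

  # a CDS candidate passing aTIS thresholds but not the CDS ones (10 < 15)
  cl3 <- clean_tis_ann(mid_codon = "GAC")  # GACGAC... contains ACG codons
  cand <- enumerate_tis_candidates(cl3$ann, "TX1")
  acg <- cand[codon == "ACG" & category == "CDS"][.N]  # far from the aTIS
  init3 <- toy_profile(rep("chr1", 2), rep("+", 2),
                       c(acg$genomic_pos, cl3$atis_tx),
                       c(10L, 50L), condition = "initiating")
  calls3 <- call_tis(cl3$ann, init3, elong, translated = "TX1")
  expect_equal(nrow(calls3[category == "CDS"]), 0L)
})

test_that("rule (i) keeps the 5'-most candidate on a window-maximum tie", {
  # two CTG candidates 3 nt apart in the 5'UTR with equal accumulated counts
  utr5 <- paste0(strrep("C", 9), "CTGCTG", strrep("C", 5))  # at 10 and 13
  cl <- clean_tis_ann(utr5 = utr5)
  init <- toy_profile(rep("chr1", 2), rep("+", 2), c(10L, 13L),
                      c(15L, 15L), condition = "initiating")
  elong <- toy_profile("chr1", "+", cl$atis_tx + 30L, 10L)
  calls <- call_tis(cl$ann, init, elong, translated = character())
  u <- calls[category == "5UTR"]
  expect_equal(nrow(u), 1L)
  expect_equal(u$tx_pos, 10L)
})

test_that("raising thresholds never increases retained non-aTIS calls", {
  truth <- fixture_bundle_cache()
  p_ltm <- build_profile(truth$ltm_sam, "initiating", "leq15")
  p_chx <- build_profile(truth$chx_sam, "elongating", "leq15")
  tc <- call_transcripts(truth$ann, p_chx)
  translated <- tc[is_translated == TRUE, transcript_id]
  n_prev <- Inf
  for (f in c(1, 2, 4, 8)) {
    par <- default_tis_params()
    par$min_count <- par$min_count * f
    par$delta_R <- par$delta_R * f
    calls <- call_tis(truth$ann, p_ltm, p_chx, params = par,
                      translated = translated)
    n <- nrow(calls[category != "aTIS"])
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("emitted R values match brute-force recomputation from raw profiles", {
  truth <- fixture_bundle_cache()
  ann <- truth$ann
  p_ltm <- build_profile(truth$ltm_sam, "initiating", "leq15")
  p_chx <- build_profile(truth$chx_sam, "elongating", "leq15")
  tc <- call_transcripts(ann, p_chx)
  calls <- call_tis(ann, p_ltm, p_chx,
                    translated = tc[is_translated == TRUE, transcript_id])
  for (i in seq_len(nrow(calls))) {
    tid <- calls$transcript_id[i]
    m <- ann$transcripts[tid]
    pos <- tx_positions(ann, tid)
    lk <- function(prof, p) {
      w <- p + (-1L:1L); w <- w[w >= 1L & w <= length(pos)]
      sum(ribodb:::profile_counts_at(prof, m$chrom, m$strand, pos[w]))
    }
    N_i <- sum(ribodb:::profile_counts_at(p_ltm, m$chrom, m$strand, pos))
    N_e <- sum(ribodb:::profile_counts_at(p_chx, m$chrom, m$strand, pos))
    X_i <- lk(p_ltm, calls$tx_pos[i])
    expect_identical(calls$X_init[i], X_i)
    if (N_i > 0) expect_identical(calls$R_init[i], (X_i / N_i) * 10)
    if (N_e > 0)
      expect_identical(calls$R_elong[i],
                       (lk(p_chx, calls$tx_pos[i]) / N_e) * 10)
  }
})
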