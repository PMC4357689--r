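tis_row <- function(tid, tx_pos, gpos, codon, category,
                    status = NA_character_) {
  data.table::data.table(
    transcript_id = tid, tx_pos = tx_pos, genomic_pos = gpos,
    codon = codon, near_cognate = !codon == "ATG", category = category,
    X_init = 10L, X_elong = 0L, N_init = 10L, N_elong = 0L,
    R_init = 10, R_elong = 0, status = status, retained = TRUE)
}

# plus-strand transcript whose sequence IS the chromosome prefix
seq_ann <- function(txseq, utr5 = 0L, cds_len = NA_integer_) {
  if (is.na(cds_len))
    toy_ann(list(mk_tx("TX1", "G1", "chr1", "+", "lincRNA", 1L,
                       nchar(txseq))),
            list(chr1 = paste0(txseq, strrep("G", 20))))
  else simple_coding_ann(txseq, utr5, cds_len)
}

test_that("translation runs from the TIS to the first in-frame stop", {
  ann <- seq_ann("ATGGCTTAACCCCCCCCCCCCCCCCCC", 0L, 9L)
  r <- translate_from_tis(ann, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                          min_len = 1L)
  expect_equal(r$sequence, "MA")
  expect_false(r$truncated)

  # near-cognate start recodes to initiator methionine
  ann2 <- seq_ann("CTGGCTTAACCCCCCCCCCCCCCCCCC", 0L, 9L)
  r2 <- translate_from_tis(ann2, tis_row("TX1", 1L, 1L, "CTG", "aTIS"),
                           min_len = 1L)
  expect_equal(r2$sequence, "MA")

  # no in-frame stop: truncate at the last complete codon and flag
  ann3 <- seq_ann("ATGGCTGCA", 0L, 9L)
  r3 <- translate_from_tis(ann3, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                           min_len = 1L)
  expect_equal(r3$sequence, "MAA")
  expect_true(r3$truncated)
})

test_that("variants substitute before translation; only non-synonymous in descriptor", {
  ann <- seq_ann("ATGGCTTAACCCCCCCCCCCCCCCCCC", 0L, 9L)
  vns <- data.table::data.table(chrom = "chr1", pos = 5L, ref = "C",
                                alt = "T", source = "caller",
                                transcript_id = "TX1")
  r <- translate_from_tis(ann, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                          variants = vns, min_len = 1L)
  expect_equal(nrow(r), 2L)                 # reference + variant proteoform
  expect_equal(r$sequence, c("MA", "MV"))   # GCT -> GTT = A2V
  expect_equal(r$nonsyn[2], "A2V")
  expect_true(r$has_snp[2])

  vsyn <- data.table::data.table(chrom = "chr1", pos = 6L, ref = "T",
                                 alt = "C", source = "caller",
                                 transcript_id = "TX1")
  rs <- translate_from_tis(ann, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                           variants = vsyn, min_len = 1L)
  expect_equal(rs$sequence, c("MA", "MA"))  # GCT -> GCC synonymous
  expect_equal(rs$nonsyn[2], "")            # descriptor lists no variant
  expect_false(rs$has_snp[2])
})

test_that("minus-strand variants are complemented into transcript space", {
  # transcript ATGGCTTAA on the minus strand: genome holds TTAAGCCAT
  ann <- toy_ann(list(mk_tx("TX1", "G1", "chr1", "-", "protein_coding",
                            1L, 9L, cds_lo_tx = 1L, cds_hi_tx = 9L)),
                 list(chr1 = paste0("TTAAGCCAT", strrep("G", 20))))
  # genomic pos 5 (G) is transcript position 5 (C of GCT);
  # genomic G>A means transcript C>T: GCT -> GTT = A2V
  v <- data.table::data.table(chrom = "chr1", pos = 5L, ref = "G",
                              alt = "A", source = "caller",
                              transcript_id = "TX1")
  r <- translate_from_tis(ann, tis_row("TX1", 1L, 9L, "ATG", "aTIS"),
                          variants = v, min_len = 1L)
  expect_equal(r$sequence, c("MA", "MV"))
})

test_that("ambiguous bases translate as X and short products are dropped", {
  ann <- seq_ann("ATGGNTTAACCCCCCCCCCCCCCCCCC", 0L, 9L)
  r <- translate_from_tis(ann, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                          min_len = 1L)
  expect_equal(r$sequence, "MX")
  r6 <- translate_from_tis(ann, tis_row("TX1", 1L, 1L, "ATG", "aTIS"),
                           min_len = 6L)
  expect_equal(nrow(r6), 0L)
})

recs <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(
      transcript_id = r$tid, gene_id = "G", tis_tx_pos = r$tp %||% 1L,
      tis_genomic_pos = r$gp %||% 1L, chrom = "chr1", strand = "+",
      codon = "ATG", near_cognate = FALSE, category = r$cat,
      atis_status = NA_character_, sequence = r$seq,
      n_variants = r$nv %||% 0L, variants = "",
      nonsyn = r$ns %||% "", has_snp = nchar(r$ns %||% "") > 0L,
      truncated = FALSE, canonical_id = r$can %||% NA_character_)))
}

test_that("deduplication keeps the highest-ranked annotation", {
  d <- deduplicate(recs(list(tid = "A", cat = "CDS", seq = "MAK"),
                        list(tid = "B", cat = "aTIS", seq = "MAK")))
  expect_equal(nrow(d), 1L)
  expect_equal(d$category, "aTIS")
  expect_equal(d$transcript_id, "B")

  # ranking property over all category pairs
  cats <- c("aTIS", "5UTR", "CDS", "3UTR", "no_translation")
  for (i in seq_along(cats)) for (j in seq_along(cats)) {
    if (i == j) next
    d2 <- deduplicate(recs(list(tid = "A", cat = cats[i], seq = "MPQR"),
                           list(tid = "B", cat = cats[j], seq = "MPQR")))
    expect_equal(d2$category, cats[min(i, j)])
  }
})

test_that("subsequences are eliminated from the database", {
  d <- deduplicate(recs(list(tid = "A", cat = "aTIS", seq = "MA"),
                        list(tid = "B", cat = "CDS", seq = "MAK")))
  expect_equal(d$sequence, "MAK")   # "MA" is contained in "MAK"
  d3 <- deduplicate(recs(list(tid = "A", cat = "aTIS", seq = "MAKL"),
                         list(tid = "B", cat = "CDS", seq = "AKL"),
                         list(tid = "C", cat = "CDS", seq = "MXQ")))
  expect_setequal(d3$sequence, c("MAKL", "MXQ"))
})

test_that("equal-rank ties prefer variant records, then canonical, then seeded draw", {
  d <- deduplicate(recs(
    list(tid = "A", cat = "aTIS", seq = "MAK"),
    list(tid = "B", cat = "aTIS", seq = "MAK", ns = "A2V", nv = 1L)))
  expect_equal(d$transcript_id, "B")

  d2 <- deduplicate(recs(
    list(tid = "A", cat = "aTIS", seq = "MAK"),
    list(tid = "B", cat = "aTIS", seq = "MAK", can = "P001")))
  expect_equal(d2$transcript_id, "B")

  # pure tie: deterministic per seed, permutation-invariant
  r1 <- recs(list(tid = "A", cat = "aTIS", seq = "MAK"),
             list(tid = "B", cat = "aTIS", seq = "MAK"))
  r2 <- recs(list(tid = "B", cat = "aTIS", seq = "MAK"),
             list(tid = "A", cat = "aTIS", seq = "MAK"))
  expect_identical(deduplicate(r1, seed = 3L)$transcript_id,
                   deduplicate(r2, seed = 3L)$transcript_id)
  expect_identical(deduplicate(r1, seed = 3L), deduplicate(r1, seed = 3L))
})

test_that("canonical mapping uses IDs for aTIS/5'UTR and containment elsewhere", {
  r <- recs(list(tid = "A", cat = "aTIS", seq = "MAKLP"),
            list(tid = "B", cat = "CDS", seq = "KLPQ"),
            list(tid = "C", cat = "CDS", seq = "MZZZZ"))
  idmap <- data.table::data.table(transcript_id = "A",
                                  canonical_id = "SP|P1")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">SP|P2 something", "MAKLPQRST"), fa)
  m <- map_canonical(r, id_map = idmap, canonical_fasta = fa)
  expect_equal(m[transcript_id == "A", canonical_id], "SP|P1")
  expect_equal(m[transcript_id == "B", canonical_id], "SP|P2")  # contained
  expect_true(is.na(m[transcript_id == "C", canonical_id]))
})

test_that("FASTA output round-trips and supports the combined search space", {
  r <- recs(list(tid = "A", cat = "aTIS", seq = "MAKLP", can = "SP|P1"),
            list(tid = "B", cat = "5UTR", seq = "MQRST"))
  f <- tempfile(fileext = ".fa")
  write_proteoform_fasta(r, f)
  back <- parse_proteoform_fasta(f)
  expect_equal(nrow(back), 2L)
  expect_setequal(back$sequence, c("MAKLP", "MQRST"))
  expect_equal(back[grepl("^A_", id), canonical_id], "SP|P1")
  expect_equal(back[grepl("^B_", id), category], "5UTR")

  can <- tempfile(fileext = ".fa")
  writeLines(c(">SP|P1", "MAKLPXXX", ">SP|P9", "MYYY", ">SP|P8", "MWWW"),
             can)
  f2 <- tempfile(fileext = ".fa")
  write_proteoform_fasta(r, f2, canonical_fasta = can, combine = TRUE)
  all2 <- parse_proteoform_fasta(f2)
  expect_equal(nrow(all2), 4L)   # 2 records + P9 + P8 (P1 was matched)
  expect_setequal(all2$id, c("A_1", "B_1", "SP|P9", "SP|P8"))

  # empty record set in combined mode: canonical passthrough
  f3 <- tempfile(fileext = ".fa")
  write_proteoform_fasta(r[0], f3, canonical_fasta = can, combine = TRUE)
  expect_equal(nrow(parse_proteoform_fasta(f3)), 3L)
})

test_that("assembled fixture proteins back-translate consistently", {
  truth <- fixture_bundle_cache()
  ann <- truth$ann
  p_ltm <- build_profile(truth$ltm_sam, "initiating", "leq15")
  p_chx <- build_profile(truth$chx_sam, "elongating", "leq15")
  tc <- call_transcripts(ann, p_chx)
  tis <- call_tis(ann, p_ltm, p_chx,
                  translated = tc[is_translated == TRUE, transcript_id])
  vtx <- integrate_variants(ann, truth$chx_sam, truth$sample_vcf,
                            truth$dbsnp_vcf)
  rec <- assemble_proteoforms(ann, tis, vtx)
  expect_gt(nrow(rec), 0L)
  # independent re-derivation with a plain codon-table loop
  gcode <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(rec))) {
    tid <- rec$transcript_id[i]
    s <- substring(transcript_sequence(ann, tid), rec$tis_tx_pos[i])
    if (rec$n_variants[i] > 0L) {
      pos <- tx_positions(ann, tid)
      st <- ann$transcripts[tid]$strand
      vv <- vtx[transcript_id == tid]
      for (k in seq_len(nrow(vv))) {
        ti <- match(vv$pos[k], pos) - rec$tis_tx_pos[i] + 1L
        if (!is.na(ti) && ti >= 1L) {
          a <- if (st == "+") vv$alt[k] else
            c(A = "T", C = "G", G = "C", T = "A")[vv$alt[k]]
          substr(s, ti, ti) <- a
        }
      }
    }
    aa <- character(0)
    for (j in seq(1L, nchar(s) - 2L, by = 3L)) {
      cd <- substr(s, j, j + 2L)
      a1 <- if (grepl("N", cd)) "X" else gcode[[cd]]
      if (a1 == "*") break
      aa <- c(aa, a1)
    }
    prot <- paste(aa, collapse = "")
    substr(prot, 1L, 1L) <- "M"
    expect_identical(rec$sequence[i], prot)
  }
})
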