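test_that("P-site offsets follow the +12/+13/+14 length scheme", {
  expect_equal(psite_offset(26:34),
               c(12L, 12L, 12L, 12L, 12L, 13L, 13L, 13L, 14L))
  expect_true(is.na(psite_offset(25)))
  expect_true(is.na(psite_offset(35)))
  expect_equal(psite_offset(c(28, 31, 34)), c(12L, 13L, 14L))
})

test_that("build_profile places P-sites by strand-aware offset walking", {
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, c(chr1 = 10000L), list(
    list(qname = "fw28", flag = 0L, rname = "chr1", pos = 1000L,
         cigar = "28M", seq = strrep("A", 28)),
    list(qname = "rv28", flag = 16L, rname = "chr1", pos = 5000L,
         cigar = "28M", seq = strrep("A", 28)),
    list(qname = "fw31", flag = 0L, rname = "chr1", pos = 2000L,
         cigar = "31M", seq = strrep("A", 31)),
    # spliced: 10M100N18M starting at 3000; aligned ref positions are
    # 3000..3009 then 3110..3127; 13th aligned base = 3112
    list(qname = "spl", flag = 0L, rname = "chr1", pos = 3000L,
         cigar = "10M100N18M", seq = strrep("A", 28)),
    # soft-clipped: aligned query is 26 nt -> offset 12 from pos 4000
    list(qname = "clip", flag = 0L, rname = "chr1", pos = 4000L,
         cigar = "2S26M", seq = strrep("A", 28)),
    # length-rejected
    list(qname = "short", flag = 0L, rname = "chr1", pos = 6000L,
         cigar = "25M", seq = strrep("A", 25))))
  p <- build_profile(sam, "elongating", "unique")
  cnt <- function(st, pos) ribodb:::profile_counts_at(p, "chr1", st, pos)
  expect_equal(cnt("+", 1012L), 1L)            # 1000 + 12
  expect_equal(cnt("-", 5015L), 1L)            # 5027 - 12
  expect_equal(cnt("+", 2013L), 1L)            # 2000 + 13
  expect_equal(cnt("+", 3112L), 1L)            # offset walked across intron
  expect_equal(cnt("+", 4012L), 1L)            # clipped bases excluded
  expect_equal(p$total_retained, 5L)
  expect_equal(p$discarded_by_length, 1L)
})

test_that("multimapping policies drop reads by NH and counts conserve", {
  sam <- tempfile(fileext = ".sam")
  rows <- list(
    list(qname = "u", flag = 0L, rname = "chr1", pos = 100L,
         cigar = "28M", seq = strrep("A", 28), nh = 1L),
    list(qname = "m2", flag = 0L, rname = "chr1", pos = 200L,
         cigar = "28M", seq = strrep("A", 28), nh = 2L),
    list(qname = "m2", flag = 0L, rname = "chr1", pos = 300L,
         cigar = "28M", seq = strrep("A", 28), nh = 2L),
    list(qname = "m16", flag = 0L, rname = "chr1", pos = 400L,
         cigar = "28M", seq = strrep("A", 28), nh = 16L),
    list(qname = "unm", flag = 4L, seq = strrep("A", 28)))
  write_sam(sam, c(chr1 = 10000L), rows)

  pu <- build_profile(sam, "elongating", "unique")
  expect_equal(pu$total_retained, 1L)
  expect_equal(pu$discarded_by_multimap, 3L)
  expect_equal(pu$unmapped, 1L)

  pm <- build_profile(sam, "elongating", "leq15")
  expect_equal(pm$total_retained, 3L)          # both m2 locations count
  expect_equal(pm$discarded_by_multimap, 1L)   # the 16-location read
  expect_equal(ribodb:::profile_counts_at(pm, "chr1", "+", c(212L, 312L)),
               c(1L, 1L))

  # conservation over all paths
  for (p in list(pu, pm))
    expect_equal(p$total_retained + p$discarded_by_length +
                   p$discarded_by_multimap + p$unmapped, p$total_records)
})

test_that("genomic P-site arithmetic matches transcript-space computation", {
  # reads fully inside one exon: placing the P-site by genomic offset must
  # equal computing it in transcript coordinates and mapping back
  truth <- fixture_bundle_cache()
  ann <- truth$ann
  p <- build_profile(truth$ltm_sam, "initiating", "unique")
  sam <- readLines(truth$ltm_sam)
  body <- sam[!startsWith(sam, "@")]
  flds <- strsplit(body, "\t")
  simple <- Filter(function(f) !grepl("N", f[6]), flds)
  # oracle: for an ungapped alignment the P-site is start+off (fw) or
  # end-off (rv)
  oracle <- data.table::data.table(
    strand = ifelse(vapply(simple, function(f) f[2], "") == "16", "-", "+"),
    start = as.integer(vapply(simple, function(f) f[4], "")),
    len = nchar(vapply(simple, function(f) f[10], "")))
  oracle[, off := psite_offset(len)]
  oracle[, psite := ifelse(strand == "+", start + off,
                           start + len - 1L - off)]
  ocnt <- oracle[, .N, by = .(strand, psite)]
  for (i in seq_len(nrow(ocnt))) {
    got <- ribodb:::profile_counts_at(p, "chr1", ocnt$strand[i],
                                      ocnt$psite[i])
    expect_gte(got, ocnt$N[i])  # gapped reads may add to the same position
  }
})

test_that("BedGraph emission merges runs and round-trips counts", {
  prof <- toy_profile(rep("chr1", 3), rep("+", 3), c(10L, 11L, 13L),
                      c(2L, 2L, 1L))
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(prof, f, "+")
  lines <- readLines(f)
  expect_equal(lines, c("chr1\t9\t11\t2", "chr1\t12\t13\t1"))
  back <- read_bedgraph(f, "+")
  expect_equal(back[, .(chrom, strand, pos, count)],
               prof$counts[, .(chrom, strand, pos, count)])

  # sum(count x width) equals the per-strand total
  bg <- data.table::fread(f, col.names = c("c", "s0", "e", "v"))
  expect_equal(bg[, sum(v * (e - s0))], sum(prof$counts$count))

  empty <- toy_profile(character(), character(), integer(), integer())
  f2 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(empty, f2, "+")
  expect_identical(readLines(f2), character(0))
})

test_that("BedGraph round-trip is the identity on fixture profiles", {
  truth <- fixture_bundle_cache()
  p <- build_profile(truth$chx_sam, "elongating", "leq15")
  for (st in c("+", "-")) {
    f <- tempfile(fileext = ".bedgraph")
    write_bedgraph(p, f, st)
    back <- read_bedgraph(f, st)
    orig <- p$counts[st, on = "strand"][!is.na(pos)]
    data.table::setkey(back, chrom, strand, pos)
    expect_equal(back[, .(chrom, pos, count)], orig[, .(chrom, pos, count)])
  }
})
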