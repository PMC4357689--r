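# builders for small hand-made annotations, alignments and profiles

# one transcript definition in the internal GTF-emission layout:
# exon coordinates are genomic; CDS bounds are transcript coordinates
# (stop codon = last 3 nt of the CDS interval)
mk_tx <- function(tid, gid, chrom, strand, biotype, ex_s, ex_e,
                  cds_lo_tx = NA_integer_, cds_hi_tx = NA_integer_) {
  o <- order(if (strand == "+") ex_s else -ex_s)
  ex_s <- ex_s[o]; ex_e <- ex_e[o]
  w <- ex_e - ex_s + 1L
  tx_e <- cumsum(w); tx_s <- tx_e - w + 1L
  list(gid = gid, tid = tid, chrom = chrom, strand = strand,
       biotype = biotype, ex_s = ex_s, ex_e = ex_e,
       tx_ex_s = tx_s, tx_ex_e = tx_e,
       cds_lo_tx = cds_lo_tx, cds_hi_tx = cds_hi_tx)
}

# write GTF + FASTA for a list of mk_tx() transcripts and load the bundle
toy_ann <- function(txs, chrom_seqs) {
  dir <- tempfile("toyann")
  dir.create(dir)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "ann.gtf")
  writeLines(unlist(lapply(names(chrom_seqs), function(n)
    c(paste0(">", n), chrom_seqs[[n]]))), fa)
  writeLines(ribodb:::build_gtf_lines(txs, NULL), gtf)
  load_annotation(gtf, fa)
}

# hand-built P-site profile from (chrom, strand, pos, count) rows
toy_profile <- function(chrom, strand, pos, count,
                        condition = "elongating") {
  ribodb:::profile_from_counts(
    data.table::data.table(chrom = chrom, strand = strand, pos = pos,
                           count = count),
    condition = condition)
}

# minimal SAM writer: rows are lists with qname/flag/rname/pos/cigar/seq
# and optional nh; sq is a named integer vector of chromosome lengths
write_sam <- function(path, sq, rows) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- vapply(rows, function(r) {
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
            r$qname, r$flag, r$rname %||% "*", r$pos %||% 0L,
            r$cigar %||% "*", r$seq,
            strrep("I", nchar(r$seq)), r$nh %||% 1L)
  }, "")
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rep_nt <- function(x, n) strrep(x, n)

# a single-exon plus-strand protein-coding transcript over an explicit
# transcript sequence laid down at genomic position 1
simple_coding_ann <- function(txseq, utr5_len, cds_len,
                              chrom = "chr1", tid = "TX1") {
  stopifnot(utr5_len + cds_len <= nchar(txseq))
  txs <- list(mk_tx(tid, "G1", chrom, "+", "protein_coding",
                    1L, nchar(txseq),
                    cds_lo_tx = utr5_len + 1L,
                    cds_hi_tx = utr5_len + cds_len))
  toy_ann(txs, stats::setNames(list(paste0(txseq, rep_nt("G", 20))), chrom))
}

# shared full fixture bundle (built once per test run)
fixture_bundle_cache <- local({
  env <- new.env()
  function(seed = 7L) {
    key <- paste0("s", seed)
    if (is.null(env[[key]]))
      env[[key]] <- make_fixture_bundle(tempfile("bundle"), n_genes = 6L,
                                        seed = seed)
    env[[key]]
  }
})
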