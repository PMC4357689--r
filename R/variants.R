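#' Read single-nucleotide variants from a VCF file
#'
#' Reads a (plain-text or gzipped) VCF via vcfR and keeps SNV alleles:
#' one reference base substituted by one alternate base. Multi-allelic rows
#' are expanded; indels and symbolic alleles are skipped and counted.
#'
#' @param path VCF file
#' @return data.table chrom/pos/ref/alt (+ id), with attribute
#'   `n_skipped_non_snv` giving the number of skipped non-SNV alleles
#' @export
read_vcf_snvs <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.table(chrom = character(), pos = integer(),
                      id = character(), ref = character(), alt = character())
  first <- readLines(path, n = 1000L)
  if (!any(!startsWith(first, "#") & nzchar(first)) &&
      length(first) < 1000L) {
    data.table::setattr(empty, "n_skipped_non_snv", 0L)
    return(empty)  # header-only VCF
  }
  fix <- tryCatch(
    vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("unreadable VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(dim(fix)))                      # single row drops to vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || !nrow(fix)) {
    data.table::setattr(empty, "n_skipped_non_snv", 0L)
    return(empty)
  }
  d <- data.table(chrom = as.character(fix[, "CHROM"]),
                  pos = as.integer(fix[, "POS"]),
                  id = as.character(fix[, "ID"]),
                  ref = as.character(fix[, "REF"]),
                  alt = as.character(fix[, "ALT"]))
  # expand multiallelic ALT
  d <- d[, .(alt = strsplit(alt, ",", fixed = TRUE)[[1]]),
         by = .(chrom, pos, id, ref)]
  is_snv <- nchar(d$ref) == 1L & nchar(d$alt) == 1L &
    d$ref %in% c("A", "C", "G", "T") & d$alt %in% c("A", "C", "G", "T")
  out <- d[is_snv, .(chrom, pos, id, ref, alt)]
  data.table::setattr(out, "n_skipped_non_snv", sum(!is_snv))
  out
}

#' Extract reference mismatches from aligned reads
#'
#' Scans every aligned base of every mapped read against the genome and
#' collects single-base substitutions with their supporting read counts.
#' Only match/mismatch CIGAR blocks are inspected (insertions, deletions
#' and intron gaps cannot produce substitutions). SAM stores sequences on
#' the reference strand, so no strand handling is needed.
#'
#' @param path SAM or BAM file
#' @param genome DNAStringSet (e.g. the `genome` element of an annotation)
#' @return data.table chrom/pos/ref/alt/n_reads
#' @export
find_read_mismatches <- function(path, genome) {
  bam <- as_bam_path(path)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "seq"))
  if (!length(gal))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      n_reads = integer()))
  cig <- GenomicAlignments::cigar(gal)
  qranges <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  rranges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = c("M", "=", "X"), pos = GenomicAlignments::start(gal))
  seqs <- S4Vectors::mcols(gal)$seq
  chroms <- as.character(GenomicAlignments::seqnames(gal))

  rows <- vector("list", length(gal))
  for (i in seq_along(gal)) {
    qr <- qranges[[i]]; rr <- rranges[[i]]
    chr <- genome[[chroms[i]]]
    mm_pos <- integer(0); mm_ref <- character(0); mm_alt <- character(0)
    for (b in seq_along(qr)) {
      qs <- as.character(Biostrings::subseq(
        seqs[[i]], IRanges::start(qr)[b], IRanges::end(qr)[b]))
      rs <- as.character(Biostrings::subseq(
        chr, IRanges::start(rr)[b], IRanges::end(rr)[b]))
      qa <- strsplit(qs, "")[[1]]; ra <- strsplit(rs, "")[[1]]
      diffs <- which(qa != ra & qa %in% c("A", "C", "G", "T") &
                       ra %in% c("A", "C", "G", "T"))
      if (length(diffs)) {
        mm_pos <- c(mm_pos, IRanges::start(rr)[b] + diffs - 1L)
        mm_ref <- c(mm_ref, ra[diffs])
        mm_alt <- c(mm_alt, qa[diffs])
      }
    }
    if (length(mm_pos))
      rows[[i]] <- data.table(chrom = chroms[i], pos = mm_pos,
                              ref = mm_ref, alt = mm_alt)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      n_reads = integer()))
  rbindlist(rows)[, .(n_reads = .N), by = .(chrom, pos, ref, alt)]
}

#' Rescue read mismatches present in dbSNP
#'
#' Cross-checks every read substitution against a dbSNP-style reference VCF
#' and retains those whose position and alternate allele match a known
#' variant; substitutions absent from dbSNP are dropped by this path
#' (they may still enter via the external caller's VCF).
#'
#' @param mismatches data.table from [find_read_mismatches()]
#' @param dbsnp data.table from [read_vcf_snvs()] on the dbSNP VCF
#' @return data.table chrom/pos/ref/alt/n_reads/source ("dbsnp_rescue")
#' @export
rescue_dbsnp_mismatches <- function(mismatches, dbsnp) {
  mm <- as.data.table(mismatches)
  hit <- dbsnp[mm, on = c("chrom", "pos", "ref", "alt"), nomatch = NULL]
  out <- hit[, .(chrom, pos, ref, alt, n_reads)]
  out[, source := "dbsnp_rescue"]
  out[]
}

#' Merge caller variants with dbSNP-rescued mismatches
#'
#' Union of the external caller's SNVs and the rescued mismatches,
#' deduplicated by (chrom, pos, alt) with the caller taking precedence.
#' Reference alleles are validated against the genome.
#'
#' @param caller data.table from [read_vcf_snvs()] on the sample VCF (may
#'   be NULL/empty)
#' @param rescued data.table from [rescue_dbsnp_mismatches()]
#' @param genome DNAStringSet for reference validation
#' @return data.table chrom/pos/ref/alt/source
#' @export
merge_variants <- function(caller, rescued, genome) {
  parts <- list()
  if (!is.null(caller) && nrow(caller))
    parts <- c(parts, list(caller[, .(chrom, pos, ref, alt,
                                      source = "caller")]))
  if (!is.null(rescued) && nrow(rescued))
    parts <- c(parts, list(rescued[, .(chrom, pos, ref, alt, source)]))
  if (!length(parts))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      source = character()))
  v <- rbindlist(parts)
  v[, source := factor(source, levels = c("caller", "dbsnp_rescue"))]
  setorder(v, chrom, pos, alt, source)
  v <- unique(v, by = c("chrom", "pos", "alt"))
  v[, source := as.character(source)]
  gref <- vapply(seq_len(nrow(v)), function(i)
    as.character(Biostrings::subseq(genome[[v$chrom[i]]],
                                    v$pos[i], v$pos[i])), "")
  bad <- which(gref != v$ref)
  if (length(bad))
    stop("variant REF does not match genome at ",
         paste0(v$chrom[bad], ":", v$pos[bad], collapse = ", "))
  v[]
}

#' Annotate variants with overlapping transcripts
#'
#' Expands the variant list to one row per (variant, overlapping
#' transcript), using exonic overlap on either strand (a genomic variant
#' affects all isoforms containing the position).
#'
#' @param variants data.table from [merge_variants()]
#' @param ann a `RiboAnnotation`
#' @return data.table chrom/pos/ref/alt/source/transcript_id; variants
#'   overlapping no transcript are dropped (they cannot enter any protein)
#' @export
annotate_variant_transcripts <- function(variants, ann) {
  if (!nrow(variants))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      source = character(), transcript_id = character()))
  q <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(q, ann$exon_gr, ignore.strand = TRUE)
  if (!length(hits))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      source = character(), transcript_id = character()))
  d <- cbind(variants[S4Vectors::queryHits(hits)],
             data.table(transcript_id =
               ann$exon_gr$transcript_id[S4Vectors::subjectHits(hits)]))
  unique(d)
}

#' Apply the per-transcript dbSNP mismatch cap
#'
#' Counts dbSNP-rescued mismatches per transcript; whenever a transcript
#' carries more than five, its rescued mismatches are removed from the
#' final list (keeping the search database bounded). The cap is evaluated
#' per transcript: a variant removed under one over-cap transcript is
#' retained for any other transcript that stays at or under the cap.
#' Caller-produced variants are exempt. The operation is idempotent.
#'
#' @param var_tx data.table from [annotate_variant_transcripts()]
#' @param cap maximum rescued mismatches per transcript (default 5)
#' @return filtered data.table, same columns
#' @export
cap_per_transcript <- function(var_tx, cap = 5L) {
  if (!nrow(var_tx)) return(var_tx)
  n_resc <- var_tx[source == "dbsnp_rescue", .N, by = transcript_id]
  over <- n_resc[N > cap, transcript_id]
  var_tx[!(source == "dbsnp_rescue" & transcript_id %in% over)]
}

#' Full variant-integration stage
#'
#' Runs mismatch extraction, dbSNP rescue, merging with the caller VCF,
#' transcript annotation and the per-transcript cap in one call.
#'
#' @param ann a `RiboAnnotation`
#' @param alignments SAM/BAM path (elongating sample; assumed deduplicated)
#' @param sample_vcf path to the external caller's VCF, or NULL
#' @param dbsnp_vcf path to the dbSNP-style VCF, or NULL (no rescue)
#' @return data.table of per-transcript variants
#'   (chrom/pos/ref/alt/source/transcript_id)
#' @export
integrate_variants <- function(ann, alignments, sample_vcf = NULL,
                               dbsnp_vcf = NULL) {
  caller <- if (!is.null(sample_vcf)) read_vcf_snvs(sample_vcf) else NULL
  rescued <- NULL
  if (!is.null(dbsnp_vcf)) {
    mm <- find_read_mismatches(alignments, ann$genome)
    rescued <- rescue_dbsnp_mismatches(mm, read_vcf_snvs(dbsnp_vcf))
  }
  v <- merge_variants(caller, rescued, ann$genome)
  cap_per_transcript(annotate_variant_transcripts(v, ann))
}

#' Write per-transcript variants as TSV
#' @param var_tx data.table from [integrate_variants()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_variants <- function(var_tx, path) {
  fwrite(var_tx, path, sep = "\t")
  invisible(path)
}
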