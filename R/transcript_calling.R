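#' Counted CDS positions of a transcript
#'
#' The positions over which elongating footprints are counted for transcript
#' calling: the CDS minus the 15-nt windows at either end where ribosomes
#' accumulate around the start and stop codons. For protein-coding
#' transcripts with an annotated CDS of length L this is positions 16..L-15
#' (empty, and the transcript uncallable, when L <= 30). Non-protein-coding
#' transcripts have no start/stop codons, so their full exonic "CDS" is
#' counted without exclusion.
#'
#' @inheritParams tx_positions
#' @return integer vector of genomic positions in transcript orientation
#'   (may be empty)
#' @export
counted_cds_positions <- function(ann, transcript_id) {
  m <- tx_meta(ann, transcript_id)
  cs <- coding_sequence(ann, transcript_id)
  if (!isTRUE(m$has_cds)) return(cs)
  L <- length(cs)
  if (L <= 30L) return(integer(0))
  cs[16:(L - 15L)]
}

#' Length-normalized footprint count of a transcript
#'
#' Total elongating P-site count over the counted CDS positions divided by
#' the number of counted positions (CDS length minus 30 nt for annotated
#' CDS), i.e. footprints per counted nucleotide.
#'
#' @inheritParams tx_positions
#' @param profile elongating-condition `PsiteProfile`
#' @return numeric scalar; NA for uncallable transcripts (counted set empty)
#' @export
normalized_count <- function(ann, transcript_id, profile) {
  m <- tx_meta(ann, transcript_id)
  pos <- counted_cds_positions(ann, transcript_id)
  if (!length(pos)) return(NA_real_)
  sum(profile_counts_at(profile, m$chrom, m$strand, pos)) / length(pos)
}

#' Call translated transcript isoforms from elongating coverage
#'
#' A transcript is called truly translated when at least 85% of its exons
#' have a mean per-position footprint coverage (over that exon's counted
#' CDS positions) at or above the transcript-specific threshold: its mean
#' exonic footprint coverage divided by 5. Exons contributing no counted
#' positions (entirely UTR or inside the excluded start/stop windows) do
#' not enter the 85% denominator. Transcripts with no counted footprints at
#' all carry no evidence of translation and are called untranslated;
#' transcripts whose counted CDS is empty are flagged uncallable.
#'
#' The 85% comparison is exact on integers (`20 * n_pass >= 17 * n_exons`),
#' and the verdict is invariant under rescaling all counts by a positive
#' constant since the threshold scales with the mean.
#'
#' @param ann a `RiboAnnotation`
#' @param profile elongating-condition `PsiteProfile`
#' @param transcript_ids transcripts to call (default: all)
#' @return data.table of class-free calls: transcript_id, gene_id, biotype,
#'   normalized_count, threshold, n_exons (with counted positions), n_pass,
#'   fraction, is_translated, uncallable
#' @export
call_transcripts <- function(ann, profile,
                             transcript_ids = ann$transcripts$transcript_id) {
  rows <- lapply(transcript_ids, function(tid) {
    m <- tx_meta(ann, tid)
    pos <- counted_cds_positions(ann, tid)
    if (!length(pos)) {
      return(data.table(
        transcript_id = tid, gene_id = m$gene_id, biotype = m$biotype,
        normalized_count = NA_real_, threshold = NA_real_,
        n_exons = 0L, n_pass = 0L, fraction = NA_real_,
        is_translated = FALSE, uncallable = TRUE))
    }
    allpos <- tx_positions(ann, tid)
    exidx <- tx_exon_index(ann, tid)[match(pos, allpos)]
    cnt <- profile_counts_at(profile, m$chrom, m$strand, pos)
    norm <- sum(cnt) / length(pos)
    thr <- norm / 5
    exmean <- vapply(split(cnt, exidx), mean, 0)
    npass <- sum(exmean >= thr)
    nex <- length(exmean)
    data.table(
      transcript_id = tid, gene_id = m$gene_id, biotype = m$biotype,
      normalized_count = norm, threshold = thr,
      n_exons = nex, n_pass = npass, fraction = npass / nex,
      is_translated = norm > 0 && 20L * npass >= 17L * nex,
      uncallable = FALSE)
  })
  rbindlist(rows)
}

#' Write transcript calls as TSV
#' @param calls data.table from [call_transcripts()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_transcript_calls <- function(calls, path) {
  fwrite(calls, path, sep = "\t")
  invisible(path)
}
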