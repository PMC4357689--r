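#' Load genome and transcript annotation
#'
#' Parses an Ensembl-dialect GTF and a genome FASTA into a bundle of
#' transcript models plus an interval index for position lookups. Coordinates
#' are 1-based inclusive throughout (Ensembl convention); conversion to
#' 0-based half-open happens only at BedGraph emission.
#'
#' Each transcript model records its exons ordered 5'->3' in transcript
#' orientation, its biotype, and -- for protein-coding transcripts with CDS
#' features -- the genomic position of the first nucleotide of the start
#' codon (`cds_start`) and the last nucleotide of the stop codon (`cds_end`).
#' Ensembl CDS features exclude the stop codon, so the stop_codon feature is
#' folded in when present; transcripts with CDS but no annotated stop codon
#' keep the last CDS position as `cds_end` and are flagged `no_stop`.
#'
#' @param gtf_path path to a GTF file with `transcript_id`, `gene_id` and
#'   biotype attributes on exon/CDS rows
#' @param genome_path path to the matching genome FASTA
#' @return an object of class `RiboAnnotation`: a list with elements
#'   `transcripts` (data.table of per-transcript metadata), `exons` (named
#'   list of per-transcript exon tables, transcript order), `exon_gr`
#'   (GRanges interval index over all exons), and `genome` (DNAStringSet)
#' @export
load_annotation <- function(gtf_path, genome_path) {
  stopifnot(file.exists(gtf_path), file.exists(genome_path))
  gtf <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("malformed GTF '", gtf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  md <- S4Vectors::mcols(gtf)
  if (!all(c("type", "transcript_id", "gene_id") %in% colnames(md)))
    stop("GTF lacks required attributes (type/transcript_id/gene_id)")

  feat <- as.data.table(gtf)
  setnames(feat, "seqnames", "chrom")
  feat[, chrom := as.character(chrom)]
  feat[, strand := as.character(strand)]

  bad <- setdiff(unique(feat$chrom), names(genome))
  if (length(bad))
    stop("chromosome(s) in GTF absent from FASTA: ",
         paste(bad, collapse = ", "))

  # biotype: Ensembl GTFs carry transcript_biotype (or gene_biotype); some
  # dialects use 'biotype'
  bt_col <- intersect(c("transcript_biotype", "biotype", "gene_biotype"),
                      colnames(feat))
  if (!length(bt_col))
    stop("GTF lacks a transcript biotype attribute")
  feat[, biotype := as.character(.SD[[bt_col[1]]])]

  ex <- feat[type == "exon" & !is.na(transcript_id)]
  if (!nrow(ex)) stop("GTF contains no exon features")

  tx <- ex[, .(
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
    biotype = biotype[1]
  ), by = transcript_id]
  if (any(!tx$strand %in% c("+", "-")))
    stop("transcript without +/- strand in GTF")

  # exon list, ordered 5'->3' in transcript orientation
  exons <- lapply(split(ex[, .(transcript_id, start, end, strand)],
                        ex$transcript_id), function(d) {
    d <- if (d$strand[1] == "+") d[order(start)] else d[order(-start)]
    gs <- sort(d$start)
    if (nrow(d) > 1 && any(gs[-1] <= sort(d$end)[-nrow(d)]))
      stop("overlapping exons within transcript ", d$transcript_id[1])
    d[, .(start, end)]
  })
  exons <- exons[tx$transcript_id]

  # CDS bounds (stop codon folded in when annotated)
  cds_rows <- feat[type == "CDS" & !is.na(transcript_id)]
  cds <- if (nrow(cds_rows))
    cds_rows[, .(cmin = min(start), cmax = max(end)), by = transcript_id]
  else data.table(transcript_id = character(), cmin = integer(),
                  cmax = integer())
  stop_rows <- feat[type == "stop_codon" & !is.na(transcript_id)]
  stopc <- if (nrow(stop_rows))
    stop_rows[, .(smin = min(start), smax = max(end)), by = transcript_id]
  else data.table(transcript_id = character(), smin = integer(),
                  smax = integer())
  tx[, `:=`(cds_start = NA_integer_, cds_end = NA_integer_,
            has_cds = FALSE, no_stop = FALSE)]
  if (nrow(cds)) {
    m <- match(tx$transcript_id, cds$transcript_id)
    hit <- !is.na(m)
    sm <- match(tx$transcript_id, stopc$transcript_id)
    for (i in which(hit)) {
      ci <- m[i]
      plus <- tx$strand[i] == "+"
      cs <- if (plus) cds$cmin[ci] else cds$cmax[ci]
      if (!is.na(sm[i])) {
        ce <- if (plus) stopc$smax[sm[i]] else stopc$smin[sm[i]]
        ns <- FALSE
      } else {
        ce <- if (plus) cds$cmax[ci] else cds$cmin[ci]
        ns <- TRUE
      }
      tx[i, `:=`(cds_start = as.integer(cs), cds_end = as.integer(ce),
                 has_cds = TRUE, no_stop = ns)]
    }
  }

  exon_gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id,
    biotype = ex$biotype
  )

  setkey(tx, transcript_id)
  ann <- list(transcripts = tx, exons = exons, exon_gr = exon_gr,
              genome = genome)
  class(ann) <- "RiboAnnotation"
  ann
}

#' @export
print.RiboAnnotation <- function(x, ...) {
  cat("RiboAnnotation:", nrow(x$transcripts), "transcripts on",
      length(x$genome), "chromosome(s);",
      sum(x$transcripts$has_cds), "with CDS\n")
  invisible(x)
}

tx_meta <- function(ann, transcript_id) {
  i <- match(transcript_id, ann$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  ann$transcripts[i]
}

#' Genomic positions of a transcript, 5'->3'
#'
#' Expands the exon structure into the ordered vector of genomic positions
#' the transcript covers, in transcript orientation (descending coordinates
#' on the minus strand).
#'
#' @param ann a `RiboAnnotation`
#' @param transcript_id transcript identifier
#' @return integer vector of genomic positions
#' @export
tx_positions <- function(ann, transcript_id) {
  m <- tx_meta(ann, transcript_id)
  exdt <- ann$exons[[transcript_id]]
  if (m$strand == "+") {
    unlist(lapply(seq_len(nrow(exdt)),
                  function(i) exdt$start[i]:exdt$end[i]), use.names = FALSE)
  } else {
    unlist(lapply(seq_len(nrow(exdt)),
                  function(i) exdt$end[i]:exdt$start[i]), use.names = FALSE)
  }
}

# exon index (in transcript order) of each transcript position
tx_exon_index <- function(ann, transcript_id) {
  exdt <- ann$exons[[transcript_id]]
  rep(seq_len(nrow(exdt)), times = exdt$end - exdt$start + 1L)
}

#' Coding-sequence positions of a transcript
#'
#' For protein-coding transcripts with annotated CDS bounds: the exonic
#' genomic positions from the first nucleotide of the start codon through
#' the last nucleotide of the stop codon, 5'->3'. For all other transcripts
#' the CDS is defined as the full exonic region.
#'
#' @inheritParams tx_positions
#' @return integer vector of genomic positions in transcript orientation
#' @export
coding_sequence <- function(ann, transcript_id) {
  m <- tx_meta(ann, transcript_id)
  pos <- tx_positions(ann, transcript_id)
  if (!isTRUE(m$has_cds)) return(pos)
  i <- match(m$cds_start, pos)
  j <- match(m$cds_end, pos)
  if (is.na(i) || is.na(j) || j < i)
    stop("CDS bounds of ", transcript_id, " fall outside its exons")
  pos[i:j]
}

#' Spliced nucleotide sequence of a transcript
#'
#' Concatenates the exon sequences in transcript order; minus-strand
#' transcripts are reverse-complemented, so the result always reads 5'->3'.
#'
#' @inheritParams tx_positions
#' @return character scalar (ACGTN alphabet)
#' @export
transcript_sequence <- function(ann, transcript_id) {
  m <- tx_meta(ann, transcript_id)
  exdt <- ann$exons[[transcript_id]]
  chr <- ann$genome[[m$chrom]]
  if (max(exdt$end) > length(chr) || min(exdt$start) < 1L)
    stop("exon of ", transcript_id, " outside chromosome ", m$chrom)
  # exdt rows are in transcript order; extract in genomic orientation first
  parts <- lapply(seq_len(nrow(exdt)), function(i)
    Biostrings::subseq(chr, exdt$start[i], exdt$end[i]))
  s <- do.call(Biostrings::xscat,
               if (m$strand == "+") parts else rev(parts))
  if (m$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Transcripts overlapping a genomic position
#'
#' Interval-index lookup: which transcripts have an exon covering position
#' `pos` on chromosome `chrom` (optionally restricted to one strand).
#'
#' @param ann a `RiboAnnotation`
#' @param chrom chromosome name
#' @param pos 1-based genomic position
#' @param strand "+", "-" or NULL for both
#' @return character vector of transcript ids (possibly empty)
#' @export
transcripts_at <- function(ann, chrom, pos, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                              strand = strand %||% "*")
  hits <- GenomicRanges::findOverlaps(
    q, ann$exon_gr, ignore.strand = is.null(strand))
  unique(ann$exon_gr$transcript_id[S4Vectors::subjectHits(hits)])
}
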