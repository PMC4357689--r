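#' Functional region ranges for metagenic classification
#'
#' Decomposes the annotation into strand-aware genomic region sets used for
#' footprint classification. Translation-associated regions (CDS exon,
#' 5'UTR, 3'UTR, intron) are defined only for protein-coding transcripts;
#' exons of all other biotypes form the "other biotypes" set (with their
#' biotype retained for the breakdown table).
#'
#' @param ann a `RiboAnnotation`
#' @return list of GRanges: `cds_exon`, `utr5`, `utr3`, `intron`, `other`
#' @export
annotation_region_sets <- function(ann) {
  tx <- ann$transcripts
  mk <- function(dt) {
    if (!nrow(dt)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end),
                           strand = dt$strand)
  }
  cds_l <- list(); u5_l <- list(); u3_l <- list(); int_l <- list()
  oth_l <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    exdt <- ann$exons[[tid]]
    base <- data.table(chrom = tx$chrom[i], strand = tx$strand[i])
    exr <- IRanges::IRanges(sort(exdt$start), sort(exdt$end))
    if (tx$biotype[i] == "protein_coding") {
      if (isTRUE(tx$has_cds[i])) {
        lo <- min(tx$cds_start[i], tx$cds_end[i])
        hi <- max(tx$cds_start[i], tx$cds_end[i])
        cdsr <- IRanges::intersect(exr, IRanges::IRanges(lo, hi))
        left <- IRanges::intersect(exr, IRanges::IRanges(1L, lo - 1L))
        right <- IRanges::intersect(
          exr, IRanges::IRanges(hi + 1L, max(exdt$end)))
        if (tx$strand[i] == "+") { u5r <- left; u3r <- right }
        else { u5r <- right; u3r <- left }
      } else {
        # protein_coding without CDS features: whole exonic region counts
        # as coding exon (mirrors the full-exon CDS convention)
        cdsr <- exr; u5r <- IRanges::IRanges(); u3r <- IRanges::IRanges()
      }
      intr <- IRanges::setdiff(
        IRanges::IRanges(min(exdt$start), max(exdt$end)), exr)
      add <- function(lst, r) {
        if (!length(r)) return(lst)
        c(lst, list(cbind(base, data.table(start = IRanges::start(r),
                                           end = IRanges::end(r)))))
      }
      cds_l <- add(cds_l, cdsr); u5_l <- add(u5_l, u5r)
      u3_l <- add(u3_l, u3r); int_l <- add(int_l, intr)
    } else {
      d <- cbind(base, data.table(start = IRanges::start(exr),
                                  end = IRanges::end(exr)))
      d[, biotype := tx$biotype[i]]
      oth_l <- c(oth_l, list(d))
    }
  }
  other <- if (length(oth_l)) {
    d <- rbindlist(oth_l)
    gr <- mk(d); gr$biotype <- d$biotype; gr
  } else GenomicRanges::GRanges()
  list(cds_exon = mk(rbindlist(cds_l)), utr5 = mk(rbindlist(u5_l)),
       utr3 = mk(rbindlist(u3_l)), intron = mk(rbindlist(int_l)),
       other = other)
}

#' Metagenic classification of P-sites
#'
#' Assigns every P-site of a unique-mapper profile to exactly one functional
#' category. Within protein-coding transcripts the precedence is CDS exon >
#' 5'UTR > 3'UTR > intron (a position classified better by any overlapping
#' protein-coding transcript takes the better category); positions matched
#' only by non-protein-coding transcripts are "other_biotypes" (with a
#' per-biotype breakdown); everything else is "intergenic". Classification
#' is strand-matched: a P-site only counts toward transcripts on its own
#' strand.
#'
#' @param profile a `PsiteProfile` built with `multimap = "unique"`
#' @param ann a `RiboAnnotation`
#' @return list of class `MetagenicCounts`: `counts` (named integer vector
#'   over the six categories, weighted by P-site count) and
#'   `biotype_breakdown` (named integer vector for other_biotypes)
#' @export
classify_psites <- function(profile, ann) {
  regions <- annotation_region_sets(ann)
  d <- profile$counts
  cats <- c("exon", "5UTR", "3UTR", "intron", "other_biotypes", "intergenic")
  if (!nrow(d)) {
    out <- list(counts = stats::setNames(integer(length(cats)), cats),
                biotype_breakdown = integer(0))
    class(out) <- "MetagenicCounts"
    return(out)
  }
  q <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos),
                              strand = d$strand)
  assigned <- rep(NA_character_, nrow(d))
  order_sets <- list(exon = regions$cds_exon, `5UTR` = regions$utr5,
                     `3UTR` = regions$utr3, intron = regions$intron,
                     other_biotypes = regions$other)
  for (nm in names(order_sets)) {
    if (!length(order_sets[[nm]])) next
    ov <- IRanges::overlapsAny(q, order_sets[[nm]], ignore.strand = FALSE)
    assigned[is.na(assigned) & ov] <- nm
  }
  assigned[is.na(assigned)] <- "intergenic"
  counts <- vapply(cats, function(cc) sum(d$count[assigned == cc]), 0L)

  breakdown <- integer(0)
  oth <- which(assigned == "other_biotypes")
  if (length(oth) && length(regions$other)) {
    hits <- GenomicRanges::findOverlaps(q[oth], regions$other,
                                        ignore.strand = FALSE,
                                        select = "first")
    bt <- regions$other$biotype[hits]
    breakdown <- vapply(split(d$count[oth], bt), sum, 0L)
  }
  out <- list(counts = counts, biotype_breakdown = breakdown)
  class(out) <- "MetagenicCounts"
  out
}

#' @export
print.MetagenicCounts <- function(x, ...) {
  cat("Metagenic P-site classification:\n")
  print(x$counts)
  if (length(x$biotype_breakdown)) {
    cat("other biotypes breakdown:\n")
    print(x$biotype_breakdown)
  }
  invisible(x)
}

#' Per-gene footprint counts
#'
#' Sums unique-mapper P-site counts over the exon union of each gene
#' (strand-matched). Genes without any footprint appear with count 0.
#'
#' @inheritParams classify_psites
#' @return data.table with gene_id and count, all annotated genes present
#' @export
gene_counts <- function(profile, ann) {
  genes <- unique(ann$transcripts$gene_id)
  d <- profile$counts
  res <- data.table(gene_id = genes, count = 0L)
  if (nrow(d)) {
    q <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos),
                                strand = d$strand)
    hits <- GenomicRanges::findOverlaps(q, ann$exon_gr,
                                        ignore.strand = FALSE)
    if (length(hits)) {
      hg <- data.table(
        gene_id = ann$exon_gr$gene_id[S4Vectors::subjectHits(hits)],
        qi = S4Vectors::queryHits(hits))
      hg <- unique(hg)  # count a P-site once per gene, not per exon
      hg[, count := d$count[qi]]
      agg <- hg[, .(count = sum(count)), by = gene_id]
      res[agg, count := i.count, on = "gene_id"]
    }
  }
  setorder(res, -count, gene_id)
  res[]
}

#' Gene-level distribution summaries
#'
#' Produces the three gene-distribution summaries over per-gene footprint
#' counts: a ranked abundance table (highest to lowest), the cumulative
#' fraction of footprints along that ranking, and a kernel density of
#' log10(count + 1).
#'
#' @param gc data.table from [gene_counts()]
#' @return list with `ranked` (gene_id, count, rank, fraction, cumulative)
#'   and `density` (data.table x/y; NULL when no counts)
#' @export
gene_distribution <- function(gc) {
  gc <- as.data.table(gc)
  setorder(gc, -count, gene_id)
  total <- sum(gc$count)
  ranked <- data.table(gene_id = gc$gene_id, count = gc$count,
                       rank = seq_len(nrow(gc)))
  ranked[, fraction := if (total > 0) count / total else 0]
  ranked[, cumulative := cumsum(fraction)]
  dens <- NULL
  if (nrow(gc) >= 2 && total > 0) {
    dd <- stats::density(log10(gc$count + 1))
    dens <- data.table(x = dd$x, y = dd$y)
  }
  list(ranked = ranked[], density = dens)
}

#' Write QC tables
#'
#' Writes the metagenic classification, biotype breakdown, gene counts and
#' gene-distribution tables as tab-separated files.
#'
#' @param mg a `MetagenicCounts`
#' @param gc data.table from [gene_counts()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_qc_tables <- function(mg, gc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(data.table(category = names(mg$counts), count = mg$counts),
         file.path(out_dir, "metagenic_classification.tsv"), sep = "\t")
  fwrite(data.table(biotype = names(mg$biotype_breakdown),
                    count = as.integer(mg$biotype_breakdown)),
         file.path(out_dir, "biotype_breakdown.tsv"), sep = "\t")
  fwrite(gc, file.path(out_dir, "gene_counts.tsv"), sep = "\t")
  gd <- gene_distribution(gc)
  fwrite(gd$ranked, file.path(out_dir, "gene_distribution.tsv"), sep = "\t")
  invisible(out_dir)
}
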