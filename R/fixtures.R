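# codons that never terminate translation (used to build open reading frames)
NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# split a transcript of length L into n exon segments of length >= min_len
split_exons <- function(L, n, min_len = 8L) {
  if (n == 1L) return(data.table(s = 1L, e = L))
  stopifnot(L >= n * min_len)
  repeat {
    cuts <- sort(sample(seq_len(L - 1L), n - 1L))
    lens <- diff(c(0L, cuts, L))
    if (all(lens >= min_len)) break
  }
  e <- cumsum(lens)
  data.table(s = c(1L, e[-n] + 1L), e = e)
}

#' Generate a deterministic toy genome with annotation
#'
#' Builds a small multi-gene genome with Ensembl-style GTF annotation and
#' known ground truth for every downstream stage. Each gene carries one or
#' two transcripts; roughly three quarters of the genes are protein-coding
#' (5'UTR of 24-60 nt with one planted near-cognate start codon, a CDS of
#' 60-240 nt opening with ATG and closing with a stop codon, a 3'UTR of
#' 20-60 nt, 1-8 exons) and the rest are lincRNAs (1-3 exons). Genes
#' alternate between strands and are separated by intergenic spacers.
#' About 80% of protein-coding and half of lincRNA transcripts are marked
#' translated in the truth table; translated protein-coding transcripts get
#' an annotated-start TIS in the truth, and alternating ones additionally a
#' 5'UTR near-cognate TIS and (where available) a downstream in-CDS TIS.
#' Output is byte-identical for a given seed.
#'
#' @param n_genes number of genes (>= 1)
#' @param seed integer seed
#' @param out_dir directory for `genome.fa` and `annotation.gtf`
#' @return object of class `FixtureTruth`: list with file paths, the loaded
#'   `RiboAnnotation`, and truth tables `transcripts` and `tis`
#' @export
make_genome <- function(n_genes, seed = 1L, out_dir = tempfile("fix")) {
  stopifnot(n_genes >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    chrom_seq <- character(0)
    gtf <- list()
    tx_truth <- list()
    tis_truth <- list()   # transcript-relative; genomic filled in later
    offset <- 0L
    chrom <- "chr1"
    near <- c("CTG", "GTG", "TTG", "ACG", "ATT", "ATC")

    for (g in seq_len(n_genes)) {
      gid <- sprintf("GENE%03d", g)
      strand <- if (g %% 2L == 1L) "+" else "-"
      is_pc <- stats::runif(1) < 0.75 || g <= 2L  # ensure coding genes exist
      spacer <- sample(200:400, 1L)

      if (is_pc) {
        utr5 <- sample(24:60, 1L)
        n_cod <- sample(20:80, 1L)          # incl. start & stop
        cds_len <- 3L * n_cod
        utr3 <- sample(20:60, 1L)
        L <- utr5 + cds_len + utr3
        txseq <- paste0(
          rand_nt(utr5),
          "ATG",
          paste(sample(NONSTOP_CODONS, n_cod - 2L, replace = TRUE),
                collapse = ""),
          sample(c("TAA", "TAG", "TGA"), 1L),
          rand_nt(utr3))
        # plant one near-cognate start in the 5'UTR, clear of the aTIS,
        # far enough in that a footprint P-site (offset >= 12) can reach
        # it, out of frame with the CDS (so the uORF product is not a 5'
        # extension subsuming the annotated product) and with an ORF long
        # enough to be identifiable (>= 6 aa)
        base <- txseq
        repeat {
          nc_pos <- sample(14:(utr5 - 4L), 1L)
          if ((nc_pos - (utr5 + 1L)) %% 3L == 0L) next
          nc_codon <- sample(near, 1L)
          txseq <- base
          substr(txseq, nc_pos, nc_pos + 2L) <- nc_codon
          if (nchar(translate_orf(substring(txseq, nc_pos))$aa) >= 6L) break
        }
        n_ex <- sample(1:8, 1L)
        if (L < n_ex * 30L) n_ex <- max(1L, L %/% 30L)
        ex <- split_exons(L, n_ex, min_len = 12L)
        translated <- stats::runif(1) < 0.8 || g <= 2L
        biotype <- "protein_coding"
        cds_lo_tx <- utr5 + 1L; cds_hi_tx <- utr5 + cds_len
      } else {
        L <- sample(120:400, 1L)
        txseq <- rand_nt(L)
        n_ex <- sample(1:3, 1L)
        if (L < n_ex * 35L) n_ex <- max(1L, L %/% 35L)
        ex <- split_exons(L, n_ex, min_len = 30L)
        translated <- stats::runif(1) < 0.5
        biotype <- "lincRNA"
        utr5 <- NA_integer_; cds_lo_tx <- NA_integer_; cds_hi_tx <- NA_integer_
        nc_pos <- NA_integer_; nc_codon <- NA_character_
      }

      introns <- if (n_ex > 1L) sample(30:200, n_ex - 1L, replace = TRUE)
                 else integer(0)

      # lay exons and introns out 5'->3' on a local plus-strand canvas
      piece <- character(0)
      ex_rel <- integer(0)  # relative start of each exon on the canvas
      at <- 1L
      for (i in seq_len(n_ex)) {
        exseq <- substr(txseq, ex$s[i], ex$e[i])
        piece <- c(piece, exseq)
        ex_rel <- c(ex_rel, at)
        at <- at + nchar(exseq)
        if (i < n_ex) {
          piece <- c(piece, rand_nt(introns[i]))
          at <- at + introns[i]
        }
      }
      piece <- paste(piece, collapse = "")
      P <- nchar(piece)
      ex_w <- ex$e - ex$s + 1L
      if (strand == "+") {
        rel_s <- ex_rel
        rel_e <- ex_rel + ex_w - 1L
      } else {
        piece <- revcomp(piece)
        rel_s <- P - (ex_rel + ex_w - 1L) + 1L
        rel_e <- P - ex_rel + 1L
      }
      gstart <- offset + spacer + 1L
      abs_s <- gstart + rel_s - 1L
      abs_e <- gstart + rel_e - 1L
      chrom_seq <- c(chrom_seq, rand_nt(spacer), piece)
      offset <- offset + spacer + P

      # one or two transcripts per gene: the second (when the first exon is
      # entirely 5'UTR) drops that exon, giving a shorter-UTR isoform
      tx_defs <- list(list(idx = seq_len(n_ex), suffix = "T1"))
      if (is_pc && n_ex >= 3L && ex$e[1] < utr5)
        tx_defs <- c(tx_defs, list(list(idx = 2:n_ex, suffix = "T2")))

      for (td in tx_defs) {
        tid <- paste0(gid, ".", td$suffix)
        sel <- td$idx
        tx_truth[[tid]] <- data.table(
          transcript_id = tid, gene_id = gid, chrom = chrom,
          strand = strand, biotype = biotype,
          translated = translated && td$suffix == "T1")
        # transcript-relative features for the GTF
        drop_nt <- if (identical(sel, seq_len(n_ex))) 0L else ex$e[1]
        gtf[[length(gtf) + 1L]] <- list(
          gid = gid, tid = tid, chrom = chrom, strand = strand,
          biotype = biotype,
          ex_s = abs_s[sel], ex_e = abs_e[sel],
          tx_ex_s = ex$s[sel], tx_ex_e = ex$e[sel],
          cds_lo_tx = cds_lo_tx, cds_hi_tx = cds_hi_tx)
        if (is_pc && translated && td$suffix == "T1") {
          tis_truth[[length(tis_truth) + 1L]] <- data.table(
            transcript_id = tid, tx_pos = utr5 + 1L, codon = "ATG",
            category = "aTIS")
          if (g %% 2L == 1L)
            tis_truth[[length(tis_truth) + 1L]] <- data.table(
              transcript_id = tid, tx_pos = nc_pos, codon = nc_codon,
              category = "5UTR")
        }
      }
    }

    genome_str <- paste(c(chrom_seq, rand_nt(150L)), collapse = "")

    # write genome FASTA
    genome_fa <- file.path(out_dir, "genome.fa")
    gl <- nchar(genome_str)
    fasta_lines <- c(paste0(">", chrom),
                     substring(genome_str, seq(1L, gl, 70L),
                               pmin(seq(1L, gl, 70L) + 69L, gl)))
    writeLines(fasta_lines, genome_fa)

    # write GTF
    gtf_path <- file.path(out_dir, "annotation.gtf")
    writeLines(build_gtf_lines(gtf, genome_str), gtf_path)

    ann <- load_annotation(gtf_path, genome_fa)
    transcripts <- rbindlist(tx_truth)
    tis <- if (length(tis_truth)) rbindlist(tis_truth) else
      data.table(transcript_id = character(), tx_pos = integer(),
                 codon = character(), category = character())
    # resolve genomic coordinates of planted TIS and self-check codons
    if (nrow(tis)) {
      tis[, genomic_pos := NA_integer_]
      for (i in seq_len(nrow(tis))) {
        pos <- tx_positions(ann, tis$transcript_id[i])
        sq <- transcript_sequence(ann, tis$transcript_id[i])
        p <- tis$tx_pos[i]
        stopifnot(substr(sq, p, p + 2L) == tis$codon[i])
        tis[i, genomic_pos := pos[p]]
      }
    }
    # add a planted downstream-CDS TIS on every third coding gene, at an
    # existing candidate codon at least 10 codons into the CDS
    # planted TIS must yield identifiable products: ORF of >= 6 aa, and for
    # CDS TIS an out-of-frame codon (in-frame downstream starts give
    # N-terminal truncations that redundancy elimination removes by design)
    orf_len <- function(tid, p) {
      nchar(translate_orf(substring(transcript_sequence(ann, tid), p))$aa)
    }
    pc <- transcripts[biotype == "protein_coding" & translated == TRUE]
    for (tid in pc$transcript_id[seq_along(pc$transcript_id) %% 3L == 0L]) {
      cand <- enumerate_tis_candidates(ann, tid)
      m <- tx_meta(ann, tid)
      ci <- match(m$cds_start, tx_positions(ann, tid))
      cds_cand <- cand[category == "CDS" & tx_pos >= ci + 30L &
                         (tx_pos - ci) %% 3L != 0L]
      cds_cand <- cds_cand[vapply(tx_pos, function(p)
        orf_len(tid, p) >= 6L, TRUE)]
      if (nrow(cds_cand)) {
        pick <- cds_cand[sample(.N, 1L)]
        tis <- rbind(tis, pick[, .(transcript_id, tx_pos, codon, category,
                                   genomic_pos)])
      }
    }
    # a planted TIS on every translated lincRNA (no_translation category)
    lc <- transcripts[biotype != "protein_coding" & translated == TRUE]
    for (tid in lc$transcript_id) {
      cand <- enumerate_tis_candidates(ann, tid)
      Lt <- nchar(transcript_sequence(ann, tid))
      cc <- cand[tx_pos >= 16L & tx_pos <= Lt - 40L]
      cc <- cc[vapply(tx_pos, function(p) orf_len(tid, p) >= 6L, TRUE)]
      if (nrow(cc)) {
        pick <- cc[sample(.N, 1L)]
        tis <- rbind(tis, pick[, .(transcript_id, tx_pos, codon, category,
                                   genomic_pos)])
      }
    }

    truth <- list(dir = out_dir, genome_fasta = genome_fa, gtf = gtf_path,
                  ann = ann, transcripts = transcripts, tis = tis,
                  variants = NULL, seed = seed)
    class(truth) <- "FixtureTruth"
    truth
  })
}

# Ensembl-style GTF emission: gene/transcript/exon/CDS/UTR/start/stop rows
build_gtf_lines <- function(gtf, genome_str) {
  lines <- character(0)
  attr_str <- function(gid, tid, biotype)
    sprintf(paste0("gene_id \"%s\"; transcript_id \"%s\"; ",
                   "gene_biotype \"%s\"; transcript_biotype \"%s\";"),
            gid, tid, biotype, biotype)
  row <- function(chrom, type, s, e, strand, attrs)
    sprintf("%s\tribodb\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strand, attrs)
  for (t in gtf) {
    a <- attr_str(t$gid, t$tid, t$biotype)
    n_ex <- length(t$ex_s)
    lines <- c(lines, row(t$chrom, "transcript", min(t$ex_s), max(t$ex_e),
                          t$strand, a))
    for (i in seq_len(n_ex))
      lines <- c(lines, row(t$chrom, "exon", t$ex_s[i], t$ex_e[i],
                            t$strand, a))
    if (!is.na(t$cds_lo_tx)) {
      # project transcript-relative CDS/UTR/codon intervals onto exons
      proj <- function(lo, hi, type) {
        for (i in seq_len(n_ex)) {
          s <- max(lo, t$tx_ex_s[i]); e <- min(hi, t$tx_ex_e[i])
          if (s > e) next
          # offset within this exon (transcript-relative), then to genome
          if (t$strand == "+") {
            gs <- t$ex_s[i] + (s - t$tx_ex_s[i])
            ge <- t$ex_s[i] + (e - t$tx_ex_s[i])
          } else {
            ge <- t$ex_e[i] - (s - t$tx_ex_s[i])
            gs <- t$ex_e[i] - (e - t$tx_ex_s[i])
          }
          lines <<- c(lines, row(t$chrom, type, gs, ge, t$strand, a))
        }
      }
      lo <- t$cds_lo_tx; hi <- t$cds_hi_tx
      if (lo > 1L) proj(1L, lo - 1L, "five_prime_utr")
      proj(lo, hi - 3L, "CDS")             # Ensembl CDS excludes the stop
      proj(lo, lo + 2L, "start_codon")
      proj(hi - 2L, hi, "stop_codon")
      tx_len <- max(t$tx_ex_e)
      if (hi < tx_len) proj(hi + 1L, tx_len, "three_prime_utr")
    }
  }
  lines
}
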