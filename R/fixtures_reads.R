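# read-length distribution of the simulated footprints (26..34 nt)
RPF_LEN_PROBS <- c(`26` = 0.04, `27` = 0.07, `28` = 0.16, `29` = 0.18,
                   `30` = 0.20, `31` = 0.14, `32` = 0.10, `33` = 0.07,
                   `34` = 0.04)

#' Plant sequence variants into a fixture
#'
#' Chooses `n` single-nucleotide variants inside the CDS of translated
#' protein-coding transcripts (clear of start/stop codons and planted TIS
#' codons, and never creating a premature stop). Every planted variant is
#' carried by all simulated reads covering it. Variants are split between
#' an external-caller VCF and a dbSNP-style VCF: when `n >= 6` the first
#' six are concentrated on one transcript and appear in dbSNP only, so the
#' per-transcript mismatch cap is exercised; the remainder cycle through
#' caller+dbSNP, dbSNP-only, caller-only and neither.
#'
#' @param truth a `FixtureTruth` from [make_genome()]
#' @param n number of variants (>= 0)
#' @param seed integer seed
#' @return the truth with `$variants` (chrom/pos/ref/alt/transcript_id/
#'   in_caller/in_dbsnp/cap_target) and `$sample_vcf`/`$dbsnp_vcf` paths set
#' @export
plant_variants <- function(truth, n = 12L, seed = 1L) {
  stopifnot(inherits(truth, "FixtureTruth"), n >= 0L)
  ann <- truth$ann
  with_local_seed(seed, {
    pc <- truth$transcripts[biotype == "protein_coding" &
                              translated == TRUE]
    vars <- list()
    if (n > 0L && nrow(pc)) {
      cap_target <- pc$transcript_id[1L]
      # candidate CDS-internal transcript positions per transcript
      cand_pos <- lapply(pc$transcript_id, function(tid) {
        m <- tx_meta(ann, tid)
        pos <- tx_positions(ann, tid)
        ci <- match(m$cds_start, pos); cj <- match(m$cds_end, pos)
        keep <- (ci + 3L):(cj - 3L)
        planted <- truth$tis[transcript_id == tid]
        if (nrow(planted))
          for (p in planted$tx_pos)
            keep <- keep[abs(keep - p) > 4L]
        keep
      })
      names(cand_pos) <- pc$transcript_id
      tx_for <- function(i) {
        if (n >= 6L && i <= 6L) cap_target
        else pc$transcript_id[1L + (i %% nrow(pc))]
      }
      used <- list()
      for (i in seq_len(n)) {
        tid <- tx_for(i)
        avail <- setdiff(cand_pos[[tid]], used[[tid]] %||% integer(0))
        # keep variants >= 3 nt apart so codon edits stay independent
        if (length(used[[tid]]))
          avail <- avail[vapply(avail, function(p)
            all(abs(p - used[[tid]]) > 2L), TRUE)]
        if (!length(avail)) next
        tp <- sample(avail, 1L)
        used[[tid]] <- c(used[[tid]] %||% integer(0), tp)
        m <- tx_meta(ann, tid)
        pos <- tx_positions(ann, tid)
        sq <- transcript_sequence(ann, tid)
        ci <- match(m$cds_start, pos)
        # pick an alt (transcript strand) that keeps the codon stop-free
        frame0 <- ci + 3L * ((tp - ci) %/% 3L)
        cod <- substr(sq, frame0, frame0 + 2L)
        ref_tx <- substr(sq, tp, tp)
        alt_ok <- setdiff(c("A", "C", "G", "T"), ref_tx)
        alt_ok <- alt_ok[vapply(alt_ok, function(a) {
          cc <- cod; substr(cc, tp - frame0 + 1L, tp - frame0 + 1L) <- a
          !cc %in% c("TAA", "TAG", "TGA")
        }, TRUE)]
        if (!length(alt_ok)) next
        alt_tx <- sample(alt_ok, 1L)
        gpos <- pos[tp]
        ref_g <- if (m$strand == "+") ref_tx else unname(COMPLEMENT[ref_tx])
        alt_g <- if (m$strand == "+") alt_tx else unname(COMPLEMENT[alt_tx])
        grp <- if (n >= 6L && i <= 6L) "dbsnp_only"
               else c("both", "dbsnp_only", "caller_only",
                      "neither")[1L + (i %% 4L)]
        vars[[length(vars) + 1L]] <- data.table(
          chrom = m$chrom, pos = gpos, ref = ref_g, alt = alt_g,
          transcript_id = tid, tx_pos = tp,
          in_caller = grp %in% c("both", "caller_only"),
          in_dbsnp = grp %in% c("both", "dbsnp_only"),
          cap_target = n >= 6L & i <= 6L)
      }
    }
    variants <- if (length(vars)) rbindlist(vars) else
      data.table(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), transcript_id = character(),
                 tx_pos = integer(), in_caller = logical(),
                 in_dbsnp = logical(), cap_target = logical())

    vcf_header <- c("##fileformat=VCFv4.2",
                    paste0("##contig=<ID=",
                           names(ann$genome)[1], ">"),
                    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    vcf_body <- function(d, ids) {
      if (!nrow(d)) return(character(0))
      sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", d$chrom, d$pos, ids, d$ref,
              d$alt)
    }
    sample_vcf <- file.path(truth$dir, "sample.vcf")
    dbsnp_vcf <- file.path(truth$dir, "dbsnp.vcf")
    dc <- variants[in_caller == TRUE][order(pos)]
    dd <- variants[in_dbsnp == TRUE][order(pos)]
    writeLines(c(vcf_header, vcf_body(dc, rep(".", nrow(dc)))), sample_vcf)
    writeLines(c(vcf_header,
                 vcf_body(dd, sprintf("rs%06d", seq_len(nrow(dd))))),
               dbsnp_vcf)
    truth$variants <- variants
    truth$sample_vcf <- sample_vcf
    truth$dbsnp_vcf <- dbsnp_vcf
    truth
  })
}

# genomic ascending positions + variant substitution -> SAM SEQ and CIGAR
read_from_tx_span <- function(ann, truth, tid, t_from, t_to) {
  m <- tx_meta(ann, tid)
  pos <- sort(tx_positions(ann, tid)[t_from:t_to])  # ascending genomic
  brk <- which(diff(pos) != 1L)
  bs <- c(pos[1L], pos[brk + 1L])
  be <- c(pos[brk], pos[length(pos)])
  cig <- character(0)
  for (i in seq_along(bs)) {
    cig <- c(cig, paste0(be[i] - bs[i] + 1L, "M"))
    if (i < length(bs)) cig <- c(cig, paste0(bs[i + 1L] - be[i] - 1L, "N"))
  }
  chr <- ann$genome[[m$chrom]]
  seqs <- paste(vapply(seq_along(bs), function(i)
    as.character(Biostrings::subseq(chr, bs[i], be[i])), ""),
    collapse = "")
  v <- truth$variants
  if (!is.null(v) && nrow(v)) {
    vv <- v[chrom == m$chrom & pos %in% sort(tx_positions(ann, tid)[t_from:t_to])]
    vv <- unique(vv, by = "pos")
    for (k in seq_len(nrow(vv))) {
      off <- match(vv$pos[k], pos)
      substr(seqs, off, off) <- vv$alt[k]
    }
  }
  list(pos = bs[1L], cigar = paste(cig, collapse = ""), seq = seqs,
       chrom = m$chrom, flag = if (m$strand == "+") 0L else 16L)
}

#' Simulate RIBO-seq reads over a fixture
#'
#' Writes a SAM file of single-end footprint alignments whose P-sites land
#' at chosen transcript positions, with lengths drawn from 26-34 nt and the
#' matching length-dependent offsets, spliced CIGARs across introns, and
#' planted variant alleles embedded in the read sequences.
#'
#' Elongating condition (`"chx"`): every counted CDS position of each
#' translated transcript receives `depth` P-sites and the 15-nt windows at
#' the CDS start and stop receive `3 * depth` (footprint accumulation at
#' start/stop codons); untranslated transcripts receive no reads.
#' Initiating condition (`"ltm"`): each planted TIS receives `tis_depth`
#' P-sites within +/-1 nt of its first codon position (80% exactly on it),
#' plus about 5% scattered noise reads placed at least 5 nt away from any
#' planted TIS, at most two per position.
#'
#' @param truth a `FixtureTruth` (after [plant_variants()] if variants are
#'   wanted in the reads)
#' @param condition "chx" or "ltm"
#' @param depth elongating P-sites per counted CDS position
#' @param tis_depth initiating P-sites per planted TIS
#' @param seed integer seed
#' @param out_sam output path (default `<fixture dir>/<condition>.sam`)
#' @return invisibly, the SAM path
#' @export
simulate_reads <- function(truth, condition = c("chx", "ltm"), depth = 2L,
                           tis_depth = 60L, seed = 1L, out_sam = NULL) {
  condition <- match.arg(condition)
  ann <- truth$ann
  out_sam <- out_sam %||% file.path(truth$dir, paste0(condition, ".sam"))
  with_local_seed(seed, {
    recs <- list()
    emit <- function(tid, tpos_vec) {
      # one read per requested P-site transcript position
      L <- length(tx_positions(ann, tid))
      for (t in tpos_vec) {
        len <- as.integer(sample(names(RPF_LEN_PROBS), 1L,
                                 prob = RPF_LEN_PROBS))
        off <- psite_offset(len)
        t_from <- t - off
        t_to <- t_from + len - 1L
        if (t_from < 1L || t_to > L) {
          # edge of the transcript: shrink to a length that still maps
          fit <- which(vapply(26:34, function(l) {
            o <- psite_offset(l); t - o >= 1L && t - o + l - 1L <= L
          }, TRUE))
          if (!length(fit)) next
          len <- (26:34)[fit[length(fit)]]
          off <- psite_offset(len)
          t_from <- t - off; t_to <- t_from + len - 1L
        }
        recs[[length(recs) + 1L]] <<-
          c(read_from_tx_span(ann, truth, tid, t_from, t_to),
            list(tid = tid))
      }
    }

    if (condition == "chx") {
      for (tid in truth$transcripts[translated == TRUE, transcript_id]) {
        m <- tx_meta(ann, tid)
        cs <- coding_sequence(ann, tid)
        allpos <- tx_positions(ann, tid)
        ctd <- counted_cds_positions(ann, tid)
        ctd_t <- match(ctd, allpos)
        tgt <- rep(ctd_t, each = depth)
        if (isTRUE(m$has_cds) && length(cs) > 30L) {
          cs_t <- match(cs, allpos)
          Lc <- length(cs_t)
          win <- c(cs_t[1:15], cs_t[(Lc - 14L):Lc])
          tgt <- c(tgt, rep(win, each = 3L * depth))
        }
        emit(tid, tgt)
      }
    } else {
      planted <- truth$tis
      for (i in seq_len(nrow(planted))) {
        tid <- planted$transcript_id[i]
        t <- planted$tx_pos[i]
        n_on <- round(0.8 * tis_depth)
        n_j <- tis_depth - n_on
        jit <- rep(c(-1L, 1L), length.out = n_j)  # even split: no spurious
                                                  # window-maximum ties
        emit(tid, c(rep(t, n_on), t + jit))
      }
      # scattered noise, clear of every planted TIS
      for (tid in unique(planted$transcript_id)) {
        L <- length(tx_positions(ann, tid))
        ptis <- planted[transcript_id == tid, tx_pos]
        n_noise <- max(1L, round(0.05 * tis_depth *
                                   length(ptis) / 2L))
        avail <- setdiff(15:(L - 15L),
                         unlist(lapply(ptis, function(p) (p - 5L):(p + 5L))))
        if (length(avail)) {
          np <- sample(avail, min(n_noise, length(avail)))
          emit(tid, np)
        }
      }
    }

    header <- c("@HD\tVN:1.6\tSO:unknown",
                vapply(names(ann$genome), function(nm)
                  sprintf("@SQ\tSN:%s\tLN:%d", nm,
                          length(ann$genome[[nm]])), ""),
                "@PG\tID:ribodb_sim\tPN:ribodb_sim")
    body <- vapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
              sprintf("%s_r%05d", condition, i), r$flag, r$chrom, r$pos,
              r$cigar, r$seq, strrep("I", nchar(r$seq)))
    }, "")
    writeLines(c(header, body), out_sam)
  })
  invisible(out_sam)
}

#' Generate a complete fixture bundle
#'
#' Genome + annotation, planted variants, and elongating plus initiating
#' read sets, all deterministic per seed.
#'
#' @param out_dir output directory
#' @param n_genes number of genes
#' @param seed master seed; stage seeds are derived from it
#' @param depth elongating P-sites per counted CDS position
#' @param tis_depth initiating P-sites per planted TIS
#' @param n_variants planted variants
#' @return a `FixtureTruth` with `$chx_sam` and `$ltm_sam` set
#' @export
make_fixture_bundle <- function(out_dir = tempfile("fixture"), n_genes = 6L,
                                seed = 1L, depth = 2L, tis_depth = 60L,
                                n_variants = 12L) {
  truth <- make_genome(n_genes, seed = seed, out_dir = out_dir)
  truth <- plant_variants(truth, n = n_variants, seed = seed + 1000L)
  truth$chx_sam <- simulate_reads(truth, "chx", depth = depth,
                                  seed = seed + 2000L)
  truth$ltm_sam <- simulate_reads(truth, "ltm", tis_depth = tis_depth,
                                  seed = seed + 3000L)
  truth
}
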