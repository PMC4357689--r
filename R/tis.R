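# AUG plus the nine near-cognate codons (one mismatch from ATG)
TIS_CODONS <- c("ATG",
                "CTG", "GTG", "TTG",   # position 1
                "AAG", "ACG", "AGG",   # position 2
                "ATA", "ATC", "ATT")   # position 3

#' Default per-category TIS-calling parameters
#'
#' Minimum accumulated initiating count and R-difference threshold per TIS
#' category. Annotated starts (aTIS) use the permissive 5 / 0.01 setting;
#' non-annotated categories are more stringent to limit false positives,
#' most of all downstream CDS starts (15 / 0.15) where elongating occupancy
#' makes spurious peaks likely.
#'
#' @return data.table with category, min_count, delta_R
#' @export
default_tis_params <- function() {
  data.table(
    category = c("aTIS", "5UTR", "CDS", "3UTR", "no_translation"),
    min_count = c(5L, 10L, 15L, 10L, 10L),
    delta_R = c(0.01, 0.05, 0.15, 0.05, 0.05)
  )
}

#' Enumerate candidate translation-initiation codons of a transcript
#'
#' Every AUG or near-cognate codon (differing from AUG at exactly one
#' position) at every transcript position is a TIS candidate, categorized
#' by its location relative to the annotated CDS: 5UTR (upstream of the
#' annotated start), aTIS (exactly the annotated start), CDS (codon fully
#' inside the CDS, downstream of the start), 3UTR (reaching past the stop
#' codon), or no_translation for non-protein-coding transcripts.
#'
#' @inheritParams tx_positions
#' @return data.table: transcript_id, tx_pos (1-based transcript coordinate
#'   of the codon's first nt), genomic_pos, codon, near_cognate, category
#' @export
enumerate_tis_candidates <- function(ann, transcript_id) {
  m <- tx_meta(ann, transcript_id)
  seqs <- transcript_sequence(ann, transcript_id)
  n <- nchar(seqs)
  if (n < 3L)
    return(data.table(transcript_id = character(), tx_pos = integer(),
                      genomic_pos = integer(), codon = character(),
                      near_cognate = logical(), category = character()))
  starts <- seq_len(n - 2L)
  codons <- substring(seqs, starts, starts + 2L)
  keep <- codons %in% TIS_CODONS
  tx_pos <- starts[keep]
  codon <- codons[keep]
  pos <- tx_positions(ann, transcript_id)

  if (isTRUE(m$has_cds)) {
    ci <- match(m$cds_start, pos)
    cj <- match(m$cds_end, pos)
    category <- ifelse(tx_pos < ci, "5UTR",
                ifelse(tx_pos == ci, "aTIS",
                ifelse(tx_pos + 2L <= cj, "CDS", "3UTR")))
  } else {
    category <- rep("no_translation", length(tx_pos))
  }
  data.table(transcript_id = transcript_id, tx_pos = tx_pos,
             genomic_pos = pos[tx_pos], codon = codon,
             near_cognate = codon != "ATG", category = category)
}

#' Accumulated P-site count around a codon start
#'
#' Sum of P-site counts within the +/-1 nt window around the first position
#' of a codon, in transcript orientation; footprints outside this window
#' relative to the codon start are disregarded during TIS calling.
#'
#' @param profile a `PsiteProfile`
#' @param ann a `RiboAnnotation`
#' @param transcript_id transcript the codon lives on
#' @param tx_pos transcript coordinate of the codon's first nt
#' @return integer count
#' @export
accumulate_window <- function(profile, ann, transcript_id, tx_pos) {
  m <- tx_meta(ann, transcript_id)
  pos <- tx_positions(ann, transcript_id)
  win <- tx_pos + (-1L:1L)
  win <- win[win >= 1L & win <= length(pos)]
  sum(profile_counts_at(profile, m$chrom, m$strand, pos[win]))
}

#' The R occupancy statistic
#'
#' R_k = (X_k / N_k) x 10 where X_k is the accumulated read count at the
#' candidate position and N_k the total read count on the transcript for
#' condition k (initiating or elongating). Bounded in `[0, 10]`.
#'
#' @param X accumulated count at the candidate
#' @param N total count on the transcript
#' @return numeric; NA when N == 0 (undefined)
#' @export
compute_R <- function(X, N) {
  ifelse(N > 0, (X / N) * 10, NA_real_)
}

#' Call translation-initiation sites
#'
#' Evaluates every candidate codon of the given transcripts against the
#' three TIS rules: (i) its accumulated initiating count is maximal within
#' the 7-nt window centred on the codon's first nt (one codon up- and
#' downstream; among candidates tying for the maximum the 5'-most wins),
#' (ii) the accumulated count reaches the per-category minimum, and
#' (iii) R_init - R_elong meets the per-category threshold. X values are
#' accumulated over the +/-1 nt window for both conditions; N values are
#' total exonic P-site counts of the transcript. Non-aTIS candidates
#' failing any rule are discarded. Annotated starts of transcripts with
#' elongating ribosome occupancy (the `translated` set) are always emitted,
#' labelled TRUE (all rules pass), FALSE (initiating coverage present but
#' some rule fails) or NO_DATA (no accumulated initiating coverage, or no
#' initiating reads on the transcript); annotated starts of non-translated
#' transcripts are only kept when they pass all rules.
#'
#' @param ann a `RiboAnnotation`
#' @param init_profile initiating-condition (LTM/HARR) `PsiteProfile`; may
#'   be NULL, restricting output to aTIS NO_DATA rows for translated
#'   transcripts
#' @param elong_profile elongating-condition (CHX) `PsiteProfile`
#' @param params per-category thresholds, as [default_tis_params()]
#' @param translated character vector of transcript ids with elongating
#'   occupancy (from [call_transcripts()])
#' @param transcript_ids transcripts to scan (default: all)
#' @return data.table of calls: transcript_id, tx_pos, genomic_pos, codon,
#'   near_cognate, category, X_init, X_elong, N_init, N_elong, R_init,
#'   R_elong, status (aTIS only, else NA), retained
#' @export
call_tis <- function(ann, init_profile, elong_profile,
                     params = default_tis_params(),
                     translated = character(),
                     transcript_ids = ann$transcripts$transcript_id) {
  stopifnot(all(c("category", "min_count", "delta_R") %in% names(params)))
  empty_init <- is.null(init_profile)
  if (empty_init)
    init_profile <- profile_from_counts(
      data.table(chrom = character(), strand = character(),
                 pos = integer(), count = integer()),
      condition = "initiating")

  out <- lapply(transcript_ids, function(tid) {
    m <- tx_meta(ann, tid)
    pos <- tx_positions(ann, tid)
    L <- length(pos)
    cnt_i <- profile_counts_at(init_profile, m$chrom, m$strand, pos)
    cnt_e <- profile_counts_at(elong_profile, m$chrom, m$strand, pos)
    N_i <- sum(cnt_i); N_e <- sum(cnt_e)

    cand <- enumerate_tis_candidates(ann, tid)
    if (!nrow(cand)) return(NULL)

    # accumulated (+/-1 nt) counts along the transcript
    acc_at <- function(cnt, p) {
      w <- p + (-1L:1L); w <- w[w >= 1L & w <= L]; sum(cnt[w])
    }
    cand[, X_init := vapply(tx_pos, function(p) acc_at(cnt_i, p), 0L)]
    cand[, X_elong := vapply(tx_pos, function(p) acc_at(cnt_e, p), 0L)]
    cand[, `:=`(N_init = N_i, N_elong = N_e)]
    cand[, R_init := compute_R(X_init, N_init)]
    # no elongating reads on the transcript => no elongating signal at the
    # candidate either; treat R_elong as 0 rather than undefined
    cand[, R_elong := ifelse(N_elong > 0, (X_elong / N_elong) * 10, 0)]

    # rule (i): accumulated init count maximal over the 7-nt window; among
    # candidates sharing the window maximum the 5'-most wins
    acc_all <- vapply(seq_len(L), function(p) acc_at(cnt_i, p), 0L)
    cand_acc <- stats::setNames(cand$X_init, cand$tx_pos)
    rule1 <- vapply(seq_len(nrow(cand)), function(k) {
      p <- cand$tx_pos[k]
      win <- max(1L, p - 3L):min(L, p + 3L)
      mx <- max(acc_all[win])
      if (cand$X_init[k] < mx) return(FALSE)
      earlier <- cand$tx_pos[cand$tx_pos >= p - 3L & cand$tx_pos < p]
      !any(cand_acc[as.character(earlier)] == mx)
    }, logical(1))

    mi <- params$min_count[match(cand$category, params$category)]
    dr <- params$delta_R[match(cand$category, params$category)]
    rule2 <- cand$X_init >= mi
    rule3 <- !is.na(cand$R_init) & (cand$R_init - cand$R_elong >= dr)
    pass <- rule1 & rule2 & rule3 & N_i > 0L

    cand[, status := NA_character_]
    cand[, retained := FALSE]
    is_atis <- cand$category == "aTIS"
    cand[!is_atis, retained := pass[!is_atis]]
    if (any(is_atis)) {
      tr <- tid %in% translated
      no_data <- N_i == 0L | cand$X_init == 0L
      st <- ifelse(no_data[is_atis], "NO_DATA",
                   ifelse(pass[is_atis], "TRUE", "FALSE"))
      keep_atis <- pass[is_atis] | tr
      cand[is_atis, `:=`(status = st, retained = keep_atis)]
    }
    cand[retained | category == "aTIS"]
  })
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  if (!nrow(res)) return(res)
  # aTIS rows of non-translated transcripts that were not retained are
  # dropped from the emitted table
  res[retained == TRUE | (category == "aTIS" &
                          transcript_id %in% translated)]
}

#' Write TIS calls as TSV
#' @param calls data.table from [call_tis()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_tis_calls <- function(calls, path) {
  fwrite(calls, path, sep = "\t")
  invisible(path)
}
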