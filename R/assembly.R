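# annotation ranking, most plausible first
CATEGORY_RANKING <- c("aTIS", "5UTR", "CDS", "3UTR", "no_translation")

# translate an in-frame nucleotide string up to (not including) the first
# stop codon; trailing partial codon ignored; N-containing codons become X
translate_orf <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return(list(aa = "", truncated = TRUE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) list(aa = substr(aa, 1L, stop_at - 1L), truncated = FALSE)
  else list(aa = aa, truncated = TRUE)
}

# amino-acid substitutions between two translated products
aa_substitutions <- function(ref_aa, var_aa) {
  n <- min(nchar(ref_aa), nchar(var_aa))
  if (n == 0L) return(character(0))
  r <- strsplit(ref_aa, "")[[1]][seq_len(n)]
  v <- strsplit(var_aa, "")[[1]][seq_len(n)]
  d <- which(r != v)
  subs <- sprintf("%s%d%s", r[d], d, v[d])
  if (nchar(ref_aa) != nchar(var_aa))
    subs <- c(subs, sprintf("len%d>%d", nchar(ref_aa), nchar(var_aa)))
  subs
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Translate a called TIS into proteoform records
#'
#' Translates the single reading frame starting at the TIS codon through the
#' first in-frame stop within the transcript's exonic sequence. The
#' initiator codon always yields methionine (near-cognate starts are
#' recoded); codons containing N translate as X; when no in-frame stop
#' exists before the transcript end the product is truncated at the last
#' complete codon and flagged. When variants overlapping the ORF are
#' supplied, a second record is emitted with all of them applied to the
#' nucleotide sequence before translation; its descriptor lists only the
#' amino-acid-changing (non-synonymous) substitutions.
#'
#' @param ann a `RiboAnnotation`
#' @param tis one row of the [call_tis()] table
#' @param variants optional data.table of per-transcript variants
#'   (chrom/pos/ref/alt/source/transcript_id) already filtered or not; rows
#'   for other transcripts are ignored
#' @param min_len minimum protein length in aa; shorter products are
#'   dropped (too short to identify by MS)
#' @return data.table of 0-2 proteoform records
#' @export
translate_from_tis <- function(ann, tis, variants = NULL, min_len = 6L) {
  tid <- tis$transcript_id
  m <- tx_meta(ann, tid)
  txseq <- transcript_sequence(ann, tid)
  pos <- tx_positions(ann, tid)
  t0 <- tis$tx_pos
  stopifnot(t0 >= 1L, t0 <= nchar(txseq) - 2L)
  sub_ref <- substring(txseq, t0)

  ref_tr <- translate_orf(sub_ref)
  ref_aa <- ref_tr$aa
  if (nchar(ref_aa) >= 1L) substr(ref_aa, 1L, 1L) <- "M"

  rec <- function(seqs, nvar, var_str, nonsyn, trunc) data.table(
    transcript_id = tid, gene_id = m$gene_id,
    tis_tx_pos = t0, tis_genomic_pos = tis$genomic_pos,
    chrom = m$chrom, strand = m$strand,
    codon = tis$codon, near_cognate = tis$near_cognate,
    category = tis$category, atis_status = tis$status %||% NA_character_,
    sequence = seqs, n_variants = nvar, variants = var_str,
    nonsyn = nonsyn, has_snp = nchar(nonsyn) > 0L, truncated = trunc,
    canonical_id = NA_character_)

  out <- list()
  if (nchar(ref_aa) >= min_len)
    out <- c(out, list(rec(ref_aa, 0L, "", "", ref_tr$truncated)))

  v <- if (!is.null(variants) && nrow(variants))
    variants[transcript_id == tid] else NULL
  if (!is.null(v) && nrow(v)) {
    vi <- match(v$pos, pos)          # transcript coordinate of each variant
    ok <- !is.na(vi) & vi >= t0
    v <- v[ok]; vi <- vi[ok]
    if (nrow(v)) {
      alt_tx <- if (m$strand == "+") v$alt else unname(COMPLEMENT[v$alt])
      sub_var <- sub_ref
      for (k in seq_len(nrow(v)))
        substr(sub_var, vi[k] - t0 + 1L, vi[k] - t0 + 1L) <- alt_tx[k]
      var_tr <- translate_orf(sub_var)
      var_aa <- var_tr$aa
      if (nchar(var_aa) >= 1L) substr(var_aa, 1L, 1L) <- "M"
      # variants applied within the translated span (stop codon inclusive)
      span_nt <- 3L * (nchar(var_aa) + 1L)
      applied <- which((vi - t0) < span_nt)
      if (length(applied) && nchar(var_aa) >= min_len) {
        subs <- aa_substitutions(ref_aa, var_aa)
        out <- c(out, list(rec(
          var_aa, length(applied),
          paste(sprintf("%s:%d:%s>%s", v$chrom[applied], v$pos[applied],
                        v$ref[applied], v$alt[applied]), collapse = ";"),
          paste(subs, collapse = ";"), var_tr$truncated)))
      }
    }
  }
  if (!length(out))
    return(rec("", 0L, "", "", FALSE)[0])
  rbindlist(out)
}

#' Assemble proteoform records for all retained TIS calls
#'
#' @param ann a `RiboAnnotation`
#' @param tis_calls data.table from [call_tis()]; only `retained` rows are
#'   translated
#' @param variants optional per-transcript variant table from
#'   [integrate_variants()]
#' @param min_len minimum protein length in aa
#' @return data.table of proteoform records
#' @export
assemble_proteoforms <- function(ann, tis_calls, variants = NULL,
                                 min_len = 6L) {
  keep <- tis_calls[retained == TRUE]
  rows <- lapply(seq_len(nrow(keep)), function(i)
    translate_from_tis(ann, keep[i], variants, min_len))
  out <- rbindlist(rows)
  if (!nrow(out)) return(out)
  out
}

#' Map proteoforms to a canonical protein database
#'
#' ID-based mapping assigns canonical identifiers to aTIS and 5'UTR records
#' through a transcript-to-canonical table; the remaining categories (and
#' any record the table does not cover) are mapped by sequence: exact
#' identity or containment of the proteoform within a canonical entry
#' (taking the place of an alignment search), with an optional import of an
#' external alignment result (BLAST outfmt 6: query id = record id from
#' [proteoform_record_ids()]). Unmatched records keep an empty canonical id.
#'
#' @param records proteoform data.table
#' @param id_map data.table/data.frame with columns transcript_id and
#'   canonical_id, or a path to such a TSV, or NULL
#' @param canonical_fasta path to a canonical protein FASTA (or an
#'   AAStringSet), or NULL
#' @param blast_tab optional path to a tabular alignment result
#' @return records with `canonical_id` filled where matched
#' @export
map_canonical <- function(records, id_map = NULL, canonical_fasta = NULL,
                          blast_tab = NULL) {
  records <- copy(records)
  if (!nrow(records)) return(records)
  if (!is.null(id_map)) {
    if (is.character(id_map)) {
      if (!file.exists(id_map)) stop("id map not found: ", id_map)
      id_map <- fread(id_map, sep = "\t")
    }
    id_map <- as.data.table(id_map)
    stopifnot(all(c("transcript_id", "canonical_id") %in% names(id_map)))
    idx <- records$category %in% c("aTIS", "5UTR")
    mm <- match(records$transcript_id[idx], id_map$transcript_id)
    records$canonical_id[idx] <- as.character(id_map$canonical_id)[mm]
  }
  if (!is.null(canonical_fasta)) {
    cf <- if (is.character(canonical_fasta))
      Biostrings::readAAStringSet(canonical_fasta) else canonical_fasta
    names(cf) <- sub("\\s.*$", "", names(cf))
    cseq <- as.character(cf)
    todo <- which(is.na(records$canonical_id))
    for (i in todo) {
      hit <- which(vapply(cseq, function(s)
        grepl(records$sequence[i], s, fixed = TRUE), TRUE))
      if (length(hit)) records$canonical_id[i] <- names(cf)[hit[1]]
    }
  }
  if (!is.null(blast_tab) && file.exists(blast_tab)) {
    bt <- fread(blast_tab, header = FALSE, sep = "\t")
    ids <- proteoform_record_ids(records)
    todo <- which(is.na(records$canonical_id))
    mm <- match(ids[todo], bt[[1]])
    records$canonical_id[todo] <- as.character(bt[[2]])[mm]
  }
  records[]
}

#' Stable record identifiers for proteoform records
#' @param records proteoform data.table
#' @return character vector, unique per (transcript, TIS, variant status)
#' @export
proteoform_record_ids <- function(records) {
  paste0(records$transcript_id, "_", records$tis_genomic_pos,
         ifelse(records$n_variants > 0L, "_var", ""))
}

#' Eliminate redundant proteoform sequences
#'
#' Two-step redundancy elimination. (1) Records with identical sequences
#' collapse to one, keeping the most plausible annotation (aTIS > 5'UTR >
#' CDS > 3'UTR > no translation); among equal annotations a record carrying
#' non-synonymous variant information wins, then a record with an existing
#' canonical mapping, and remaining ties are broken by a seeded
#' pseudo-random draw. (2) Any sequence completely contained in another
#' surviving sequence is removed (longest sequences are fixed first, then
#' shorter ones are tested for containment). The result is deterministic
#' given the seed and invariant under permutation of the input rows.
#'
#' @param records proteoform data.table
#' @param seed integer seed for the random tie-break
#' @return non-redundant records, ordered by category rank then id
#' @export
deduplicate <- function(records, seed = 1L) {
  if (!nrow(records)) return(records)
  r <- copy(records)
  r[, rank_ := match(category, CATEGORY_RANKING)]
  r[, has_canon := !is.na(canonical_id)]
  # canonical row order, so the random draw is permutation-invariant
  setorder(r, transcript_id, tis_genomic_pos, n_variants, rank_)
  r[, tiebreak := with_local_seed(seed, stats::runif(nrow(r)))]
  setorder(r, sequence, rank_, -has_snp, -has_canon, tiebreak)
  r <- unique(r, by = "sequence")

  # subsequence elimination, longest-first
  r[, seq_len_ := nchar(sequence)]
  setorder(r, -seq_len_, sequence)
  keep <- rep(TRUE, nrow(r))
  for (i in seq_len(nrow(r))[-1]) {
    longer <- which(keep[seq_len(i - 1L)])
    if (any(vapply(longer, function(j)
      grepl(r$sequence[i], r$sequence[j], fixed = TRUE), TRUE)))
      keep[i] <- FALSE
  }
  r <- r[keep]
  setorder(r, rank_, transcript_id, tis_genomic_pos)
  r[, c("rank_", "has_canon", "tiebreak", "seq_len_") := NULL]
  r[]
}

#' Write the proteoform search space as FASTA
#'
#' One entry per record. The header grammar is
#' `>{record_id} cat={category} tis={chrom}:{pos}({strand}) codon={codon}
#' status={status|.} var={nonsyn|.} canon={canonical_id|.} trunc={0|1}`,
#' parseable with [parse_proteoform_fasta()]. With `combine = TRUE`,
#' canonical database entries not matched by any record are appended, giving
#' the combined search space.
#'
#' @param records proteoform data.table (deduplicated)
#' @param path output FASTA path
#' @param canonical_fasta canonical protein FASTA (path or AAStringSet),
#'   required when `combine = TRUE`
#' @param combine append unmatched canonical entries
#' @return invisibly, the path
#' @export
write_proteoform_fasta <- function(records, path, canonical_fasta = NULL,
                                   combine = FALSE) {
  lines <- character(0)
  wrap <- function(s) {
    if (!nchar(s)) return(character(0))
    substring(s, seq(1L, nchar(s), 60L),
              pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
  }
  if (nrow(records)) {
    ids <- proteoform_record_ids(records)
    hdr <- sprintf(
      ">%s cat=%s tis=%s:%d(%s) codon=%s status=%s var=%s canon=%s trunc=%d",
      ids, records$category, records$chrom, records$tis_genomic_pos,
      records$strand, records$codon,
      ifelse(is.na(records$atis_status), ".", records$atis_status),
      ifelse(nchar(records$nonsyn) > 0, records$nonsyn, "."),
      ifelse(is.na(records$canonical_id), ".", records$canonical_id),
      as.integer(records$truncated))
    lines <- unlist(lapply(seq_len(nrow(records)), function(i)
      c(hdr[i], wrap(records$sequence[i]))))
  }
  if (combine) {
    if (is.null(canonical_fasta))
      stop("combine = TRUE requires a canonical FASTA")
    cf <- if (is.character(canonical_fasta))
      Biostrings::readAAStringSet(canonical_fasta) else canonical_fasta
    names(cf) <- sub("\\s.*$", "", names(cf))
    matched <- unique(stats::na.omit(records$canonical_id))
    extra <- setdiff(names(cf), matched)
    lines <- c(lines, unlist(lapply(extra, function(nm)
      c(paste0(">", nm, " cat=canonical"),
        wrap(as.character(cf[[nm]]))))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a proteoform FASTA written by [write_proteoform_fasta()]
#'
#' @param path FASTA path
#' @return data.table with id, category, tis, codon, status, nonsyn,
#'   canonical_id, truncated, sequence (canonical passthrough entries carry
#'   NA in the record fields)
#' @export
parse_proteoform_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  full <- names(aa)
  id <- sub("\\s.*$", "", full)
  grab <- function(key) {
    m <- regmatches(full, regexpr(paste0(key, "=[^ ]+"), full))
    out <- rep(NA_character_, length(full))
    hit <- grepl(paste0(key, "="), full)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  data.table(
    id = id, category = grab("cat"), tis = grab("tis"),
    codon = grab("codon"), status = grab("status"),
    nonsyn = grab("var"), canonical_id = grab("canon"),
    truncated = grab("trunc"), sequence = as.character(aa))
}
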