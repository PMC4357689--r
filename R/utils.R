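#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv rbindlist setnames fread fwrite copy := .N .SD rleid
#' @import methods
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "count", "strand", "transcript_id", "gene_id",
  "biotype", "category", "codon", "tx_pos", "genomic_pos", "near_cognate",
  "alt", "ref", "source", "n_reads", "run", "grp", "start0", "seqnames",
  "group", "cw", "width", "start", "end", "idx", "offset", "min_count",
  "delta_R", "rank_", "has_snp", "has_canon", "tiebreak", "sequence_",
  "n_rescued", "canonical_id", "retained", "status", "is_translated",
  "normalized_count", "X_init", "N_init", "X_elong", "N_elong", "R_init",
  "R_elong", "fraction", "n_pass", "n_exons", "cumulative", "in_caller",
  "in_dbsnp", "qual", "flag", "cds_start", "cds_end", "has_cds",
  "qi", "i.count", "N", "type", "translated", "cap_target",
  "tis_genomic_pos", "n_variants", "nonsyn", "atis_status", "truncated",
  "has_snp"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#' @param x character scalar (ACGTN alphabet)
#' @return character scalar
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# run code with a private RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
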