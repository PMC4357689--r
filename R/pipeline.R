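#' Run the full RIBO-seq to proteoform-database pipeline
#'
#' Orchestrates the stages in order: P-site ingest, QC, transcript calling,
#' TIS calling, variant integration and translation assembly. Every stage
#' writes a standard-format artifact under `out_dir` so stages can be
#' inspected and re-loaded in isolation, and a manifest records the exact
#' parameter set. Identical configuration and inputs yield byte-identical
#' outputs (the random tie-break in redundancy elimination is seeded).
#'
#' QC uses uniquely mapped reads only; transcript calling, TIS calling and
#' database construction use the multimapper-admitting profiles (up to 15
#' locations). When no initiating sample is given, TIS calling degrades to
#' annotated starts of translated transcripts with NO_DATA status (a
#' warning is emitted).
#'
#' @param chx_bam SAM/BAM of the elongating (CHX) sample
#' @param gtf,genome annotation GTF and genome FASTA paths
#' @param out_dir output directory
#' @param ltm_bam SAM/BAM of the initiating (LTM/HARR) sample, or NULL
#' @param sample_vcf externally called variants (VCF), or NULL
#' @param dbsnp_vcf dbSNP-style VCF for mismatch rescue, or NULL
#' @param id_map transcript-to-canonical TSV (or data.frame), or NULL
#' @param canonical_fasta canonical protein FASTA, or NULL
#' @param combine_canonical append unmatched canonical entries to the FASTA
#' @param tis_params per-category thresholds ([default_tis_params()])
#' @param min_protein_len minimum protein length (aa)
#' @param seed seed for the deduplication tie-break
#' @return invisibly, a list with all stage results and output paths
#' @export
run_pipeline <- function(chx_bam, gtf, genome, out_dir,
                         ltm_bam = NULL, sample_vcf = NULL,
                         dbsnp_vcf = NULL, id_map = NULL,
                         canonical_fasta = NULL, combine_canonical = FALSE,
                         tis_params = default_tis_params(),
                         min_protein_len = 6L, seed = 1L) {
  stopifnot(file.exists(chx_bam), file.exists(gtf), file.exists(genome))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[ribodb] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ann <- stage("annotation", load_annotation(gtf, genome))

  chx_qc <- stage("ingest", build_profile(chx_bam, "elongating", "unique"))
  chx_db <- stage("ingest", build_profile(chx_bam, "elongating", "leq15"))
  ltm_db <- if (!is.null(ltm_bam))
    stage("ingest", build_profile(ltm_bam, "initiating", "leq15")) else NULL

  trk <- file.path(out_dir, "tracks")
  dir.create(trk, showWarnings = FALSE)
  stage("tracks", {
    write_bedgraph(chx_db, file.path(trk, "chx_fw.bedgraph"), "+")
    write_bedgraph(chx_db, file.path(trk, "chx_rev.bedgraph"), "-")
    if (!is.null(ltm_db)) {
      write_bedgraph(ltm_db, file.path(trk, "ltm_fw.bedgraph"), "+")
      write_bedgraph(ltm_db, file.path(trk, "ltm_rev.bedgraph"), "-")
    }
  })

  mg <- stage("qc", classify_psites(chx_qc, ann))
  gc <- stage("qc", gene_counts(chx_qc, ann))
  stage("qc", write_qc_tables(mg, gc, file.path(out_dir, "qc")))

  tcalls <- stage("transcripts", call_transcripts(ann, chx_db))
  write_transcript_calls(tcalls, file.path(out_dir, "transcript_calls.tsv"))
  translated <- tcalls[is_translated == TRUE, transcript_id]

  if (is.null(ltm_db))
    warning("no initiating sample: TIS calling restricted to annotated ",
            "starts with NO_DATA status", call. = FALSE)
  tis <- stage("tis", call_tis(ann, ltm_db, chx_db, params = tis_params,
                               translated = translated))
  write_tis_calls(tis, file.path(out_dir, "tis_calls.tsv"))

  variants <- stage("variants", integrate_variants(
    ann, chx_bam, sample_vcf = sample_vcf, dbsnp_vcf = dbsnp_vcf))
  write_variants(variants, file.path(out_dir, "variants.tsv"))

  fasta <- file.path(out_dir, "proteoforms.fasta")
  records <- stage("assemble", {
    rec <- assemble_proteoforms(ann, tis, variants,
                                min_len = min_protein_len)
    rec <- map_canonical(rec, id_map = id_map,
                         canonical_fasta = canonical_fasta)
    rec <- deduplicate(rec, seed = seed)
    write_proteoform_fasta(rec, fasta, canonical_fasta = canonical_fasta,
                           combine = combine_canonical)
    rec
  })

  manifest <- list(
    inputs = list(chx_bam = chx_bam, ltm_bam = ltm_bam, gtf = gtf,
                  genome = genome, sample_vcf = sample_vcf,
                  dbsnp_vcf = dbsnp_vcf),
    parameters = list(tis_params = as.data.frame(tis_params),
                      min_protein_len = min_protein_len, seed = seed,
                      combine_canonical = combine_canonical),
    counts = list(
      retained_psites_chx = chx_db$total_retained,
      retained_psites_ltm = if (!is.null(ltm_db)) ltm_db$total_retained
                            else 0L,
      transcripts_called = nrow(tcalls),
      transcripts_translated = length(translated),
      tis_calls = nrow(tis),
      variants = nrow(variants),
      proteoforms = nrow(records)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(annotation = ann, profile_chx_qc = chx_qc,
                 profile_chx = chx_db, profile_ltm = ltm_db,
                 metagenic = mg, gene_counts = gc,
                 transcript_calls = tcalls, translated = translated,
                 tis_calls = tis, variants = variants, records = records,
                 fasta = fasta, out_dir = out_dir))
}
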