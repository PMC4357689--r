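# ribodb

Build a proteoform protein-sequence search space from ribosome profiling.

Mass-spectrometry search engines can only identify peptides that exist in
the search database, so proteoforms missing from curated references —
5′-extended proteins, upstream ORFs, near-cognate initiation products,
variant alleles — go undetected. Ribosome profiling (RIBO-seq) observes
translation directly: footprints of elongating ribosomes (cycloheximide,
CHX) trace coding regions, and footprints of initiating ribosomes
(lactimidomycin or harringtonine, LTM/HARR) pile up at start codons.
`ribodb` turns aligned RIBO-seq reads into (i) P-site occupancy tracks and
QC summaries, (ii) the set of transcript isoforms with evidence of protein
synthesis, (iii) called translation-initiation sites (TIS), and (iv) a
non-redundant proteoform FASTA — with sequence variants applied — that can
serve directly as an MS/MS search space, alone or merged with a canonical
database such as Swiss-Prot.

## Method core

* **P-site assignment.** Alignments of 26–34 nt are assigned to the
  ribosomal P-site at an offset from the read 5′ end of +12 (≤30 nt), +13
  (31–33 nt) or +14 (34 nt), walking aligned bases only so spliced reads
  never place a P-site in an intron. QC uses unique mappers; database
  construction additionally admits reads mapping to ≤15 locations.
* **Transcript calling.** Footprints are counted over the CDS minus the
  15-nt windows at the start and stop codons (where ribosomes accumulate)
  and normalised by the remaining length (CDS − 30 nt). A transcript is
  translated when ≥85 % of its exons reach a coverage of at least its mean
  exonic coverage / 5.
* **TIS calling.** Initiating counts are accumulated in a ±1 nt window at
  every AUG or near-cognate codon. A candidate is retained when it (i) is
  the accumulated maximum within one codon up/downstream, (ii) reaches a
  per-category minimum count, and (iii) satisfies

  ```
  R_LTM/HARR − R_CHX ≥ threshold,   R_k = (X_k / N_k) × 10
  ```

  with `X_k` the windowed count at the candidate and `N_k` the total count
  on the transcript. Defaults: aTIS 5 / 0.01, 5′UTR 10 / 0.05, CDS 15 /
  0.15, 3′UTR and non-coding 10 / 0.05. Annotated starts of transcripts
  with elongating occupancy are always reported, labelled TRUE / FALSE /
  NO_DATA.
* **Variants.** SNVs from an external caller are merged with read
  mismatches rescued through a dbSNP cross-check; transcripts with more
  than five dbSNP-matched mismatches lose them (caller variants are
  exempt).
* **Assembly.** Each retained TIS is translated in its single reading
  frame to the first in-frame stop (near-cognate initiators recoded to
  Met), with variant alleles substituted beforehand and only
  non-synonymous changes annotated. Redundancy is eliminated by annotation
  ranking (aTIS > 5′UTR > CDS > 3′UTR > no translation; variant-bearing,
  then canonical-mapped records win ties, the rest by a seeded draw) and
  subsequence removal.

## Worked example

Everything is testable without external data: the package ships a
deterministic fixture generator that writes a toy genome, Ensembl-style
GTF, spliced SAM alignments for both drug conditions, and variant VCFs
with known ground truth.

```r
library(ribodb)
truth <- make_fixture_bundle("fixture", n_genes = 6, seed = 1)
res <- run_pipeline(truth$chx_sam, truth$gtf, truth$genome_fasta, "out",
                    ltm_bam = truth$ltm_sam,
                    sample_vcf = truth$sample_vcf,
                    dbsnp_vcf = truth$dbsnp_vcf, seed = 1)

res$tis_calls[, .(transcript_id, codon, category, X_init, N_init,
                  R_init, R_elong, status)]
#>    transcript_id  codon category X_init N_init   R_init   R_elong status
#> 1:    GENE001.T1    GTG     5UTR     60    123 4.878049 0.0000000   <NA>
#> 2:    GENE001.T1    ATG     aTIS     60    123 4.878049 0.2739726   TRUE
#> 3:    GENE002.T1    ATG     aTIS     60     62 9.677419 0.3448276   TRUE
#> 4:    GENE006.T1    ATG     aTIS     60    123 4.878049 0.2380952   TRUE
#> 5:    GENE006.T1    ATT      CDS     60    123 4.878049 0.1190476   <NA>
```

Every planted start — the annotated ATGs, a near-cognate GTG upstream ORF
and a downstream in-CDS ATT — is recovered: the windowed initiating count
(`X_init` = 60) towers over the transcript background, so `R_init` exceeds
`R_CHX` by far more than the category thresholds. The final database
contains each proteoform plus a variant version where planted SNVs change
the protein:

```r
res$records[, .(transcript_id, category, codon, nonsyn, len = nchar(sequence))]
#>    transcript_id category  codon nonsyn   len
#> 1:    GENE001.T1     aTIS    ATG           52
#> 2:    GENE001.T1     aTIS    ATG   A32E    52
#> 3:    GENE002.T1     aTIS    ATG           37
#> 4:    GENE002.T1     aTIS    ATG   P23S    37
#> 5:    GENE006.T1     aTIS    ATG    Y5H    63
#> 6:    GENE006.T1     aTIS    ATG           63
#> 7:    GENE001.T1     5UTR    GTG           21
#> 8:    GENE006.T1      CDS    ATT           27
```

`out/` holds BedGraph tracks per strand and condition, metagenic and
gene-distribution QC tables, per-stage TSVs, the proteoform FASTA and a
manifest of all parameters. A command-line front end with the same stages
as subcommands is installed as `exec/ribodb`.

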