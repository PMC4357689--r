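---
title: "From ribosome footprints to a proteoform search space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ribosome footprints to a proteoform search space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ribodb` converts aligned ribosome-profiling reads into a non-redundant
proteoform protein database for MS/MS searching. This vignette explains
the model behind each stage, the parameters that matter, the behaviour of
the synthetic fixture generator, and the numerical and design choices made
where more than one reasonable implementation exists.

## The measurement model

Ribosome-protected fragments are 26–34 nt; shorter or longer alignments
are treated as degradation or ligation artefacts and discarded (counted in
the profile's bookkeeping). The ribosomal P-site — the codon being
decoded — sits at a fixed distance from the fragment 5′ end that grows
with fragment length: +12 nt for fragments of at most 30 nt, +13 for
31–33 nt, +14 for 34 nt. Two assumptions are inherited from this scheme:
that adapters were clipped before alignment (hence soft-clipped bases are
excluded from the length used to pick the offset), and that the offset is
defined on the *fragment*, not the genomic span — so for spliced
alignments the offset walk skips intron gaps and a P-site can never land
in an intron. Each retained alignment contributes exactly one count at its
P-site. Multimapping reads (NH tag) are excluded for quality control and
admitted up to 15 locations for database construction, one count per
reported location; fractional 1/n weighting would be a defensible
alternative, but integer counts keep the downstream minimum-count rules
interpretable, so it was not adopted.

## Transcript calling

The per-transcript footprint count is taken over the CDS (for non-coding
transcripts, the full exonic region stands in for the CDS) excluding 15 nt
at each end, and normalised by the counted length (CDS − 30 nt).
The exclusion windows are anchored so that the start and stop codons
themselves fall inside them — the first 15 and last 15 nt of the CDS —
because their purpose is to remove the footprint accumulation *at* start
and stop codons; anchoring the windows strictly after/before the codons
would leave exactly those peaks in the count while still subtracting
30 nt from the normalisation length, which would be self-inconsistent.

A transcript is called translated when at least 85 % of its exons have a
mean per-position coverage (over that exon's counted positions) of at
least the transcript's mean exonic coverage divided by 5. Details fixed
here:

* "coverage" of an exon is the mean per-position count, not breadth;
* exons contributing no counted positions (entirely UTR, or fully inside
  an exclusion window) are left out of the 85 % denominator;
* the 85 % comparison is exact integer arithmetic
  (`20 * n_pass >= 17 * n_exons`), so 6/7 ≈ 0.857 passes;
* a transcript with zero counted footprints is called untranslated. With
  the threshold defined as mean/5, an all-zero transcript would trivially
  satisfy `0 >= 0` on every exon; absence of footprints is absence of
  evidence for translation, so the degenerate case is resolved negatively.
* transcripts whose CDS is 30 nt or shorter have no counted positions and
  are flagged uncallable rather than called either way.

The verdict is invariant under rescaling all counts by a positive
constant, since the threshold scales with the mean — a property the test
suite checks on randomised coverage vectors against an independent
brute-force implementation.

## TIS calling

Initiating-ribosome counts are accumulated at every AUG and near-cognate
codon (one mismatch from AUG: CUG GUG UUG AAG ACG AGG AUA AUC AUU) over a
±1 nt window, absorbing the sub-codon wobble of initiating footprints.
Candidates are categorized relative to the annotated CDS of their own
transcript — 5′UTR, aTIS (the annotated start), CDS, 3′UTR, or
no_translation for non-coding transcripts — and must pass three rules:

1. the accumulated count is maximal within a 7-nt window (one codon up-
   and downstream). If several *candidate* positions tie for the maximum,
   the 5′-most wins, reflecting that scanning ribosomes initiate at the
   first available start; a tie with a non-candidate position does not
   block a call since the non-candidate can never be called.
2. the accumulated count reaches the per-category minimum;
3. `R_init − R_elong` reaches the per-category threshold, with
   `R = (X/N) × 10`, `X` the windowed count at the candidate and `N` the
   transcript total (exonic positions, matching strand).

Per-category defaults (minimum count / R difference): aTIS 5 / 0.01,
5′UTR 10 / 0.05, CDS 15 / 0.15, 3′UTR 10 / 0.05, no_translation 10 / 0.05.
The permissive aTIS setting reflects that annotated starts carry strong
prior evidence; the stringent CDS setting guards the category most exposed
to false positives from elongating occupancy. All are overridable per
category (`default_tis_params()`, CLI flags).

Annotated starts are special-cased: for transcripts with elongating
occupancy they are always reported — TRUE when all rules pass, FALSE when
initiating coverage exists but a rule fails, NO_DATA when the window (or
the whole transcript) has no initiating signal — and all three statuses
enter assembly, because elongating evidence alone supports the annotated
product. Degenerate denominators are resolved as: `N_init = 0` makes R
undefined, so non-aTIS candidates are discarded and aTIS becomes NO_DATA;
`N_elong = 0` means no elongating signal anywhere, so `R_elong` is taken
as 0 rather than undefined. Candidates are evaluated per transcript; the
same genomic codon may be called on several isoforms and is collapsed
later during redundancy elimination. One initiating profile is used per
run (LTM *or* HARR); combining both would require a rule for summing
their windows that the method does not define.

## Variant integration

Externally called SNVs (a VCF from any caller) are merged with read
mismatches rescued by a dbSNP cross-check. Rescue matches on position
*and* alternate allele — the stricter of the two readings — and reference
alleles are validated against the genome. Per transcript, more than five
dbSNP-rescued mismatches is taken as evidence of a noisy alignment rather
than real variation, and all of that transcript's rescued mismatches are
dropped; the cap is evaluated per transcript, so a variant removed under
one over-cap isoform survives for an isoform that stays at or under five,
and caller-produced variants are exempt (the cap exists to bound the
rescue path, not the caller). Only substitutions are handled — indels in
input VCFs are skipped and counted — because assembly applies variants as
single-base edits. Input alignments are assumed deduplicated upstream.

## Assembly and redundancy elimination

Each retained TIS is translated in its single reading frame to the first
in-frame stop within the transcript's exonic sequence, with the initiator
always emitted as methionine (near-cognate starts are recoded), codons
containing N emitted as X, and products without an in-frame stop truncated
at the last complete codon and flagged. Variant alleles are substituted
into the nucleotide sequence *before* translation; the record descriptor
lists only amino-acid-changing variants. Per TIS, two records at most are
emitted: the reference proteoform and one with all retained variants
applied — not the 2^n per-haplotype expansion, which would inflate the
search space and dilute search confidence. Products shorter than 6 aa are
dropped (default, tunable): they are below what an MS search can
confidently identify. The genetic code is the standard table;
selenocysteine and stop read-through are not modelled.

Redundancy elimination collapses identical sequences keeping the most
plausible annotation (aTIS > 5′UTR > CDS > 3′UTR > no translation); at
equal rank a record with non-synonymous variant information wins, then one
with an existing canonical mapping, and residual ties are broken by a
seeded pseudo-random draw whose input order is canonicalised first, so the
result is permutation-invariant and reproducible. Afterwards any sequence
fully contained in a longer surviving sequence is removed
(longest-first, deterministic). In-frame downstream starts therefore
vanish into their parent proteins by construction — the expected and
intended behaviour for N-terminally truncated products.

Canonical mapping assigns IDs to aTIS/5′UTR records through a
transcript-to-canonical table, and maps the remaining records by exact or
containment matching against the canonical FASTA; an external alignment
result (tabular, query = record id) can be imported for anything still
unmatched. Containment is a conservative stand-in for local alignment: it
finds every identical-substring relationship and never produces a partial
or gapped match whose interpretation would need score thresholds.

## The fixture generator

`make_genome()` / `plant_variants()` / `simulate_reads()` build a fully
self-contained study system: a single-chromosome genome (genes alternating
strands, separated by intergenic spacers), Ensembl-style GTF (CDS rows
excluding the stop codon, with explicit start/stop_codon features), SAM
alignments with spliced CIGARs, and VCFs. The defaults emulate the
intended data conditions: ~75 % protein-coding genes with 24–60 nt 5′UTRs,
60–240 nt CDS and 1–8 exons; elongating coverage of 2 P-sites per counted
CDS position with 3× pileups in the 15-nt start/stop windows; initiating
peaks of 60 reads per planted TIS, 80 % on the exact codon position and
the rest split evenly at ±1 nt, plus ~5 % scattered noise kept ≥5 nt from
planted codons; read lengths drawn from 26–34 nt with a mode at 30 nt.
Planted TIS are placed where the model can in principle recover them: at
transcript position ≥14 (a P-site needs ≥12 nt of upstream footprint),
with an ORF of ≥6 aa, and out of frame with the annotated CDS for planted
uORF/CDS starts so their products are not removed as substrings by design.

What the generator does *not* emulate — and what passing tests therefore
do not show — includes sequencing errors and quality variation, biased
nucleotide composition, overlapping genes, heterozygosity (every read
carries the planted allele), rRNA/contaminant reads, and the shallow,
dispersed initiating coverage of real LTM/HARR libraries. The suite
demonstrates rule-exactness and internal consistency, not performance on
real libraries.

Isoforms sharing their whole CDS (the generator's second isoforms drop a
purely-5′UTR exon) are genuinely indistinguishable from elongating
coverage, and both may be called translated although only the primary
carries simulated reads; truth comparisons are therefore made on primary
isoforms.

## Sizes, determinism and limits

The test suite and the acceptance script run on bundles of 6–8 genes
(≤ 50 transcripts, ≤ 100 kb genome, a few thousand reads), which exercise
every rule at exact thresholds while keeping a full pipeline run in tens
of seconds. All randomness flows through explicit seeds (generator stages
derive sub-seeds from the master seed; the dedup tie-break has its own
seed), and a rerun with identical inputs and seed is byte-identical
across every output file. BedGraph tracks are emitted from the
database-construction profiles (0-based half-open, adjacent equal counts
merged); internally all coordinates are 1-based inclusive, converted only
at the BedGraph boundary.

Known limitations: no periodicity/frame-based ORF scoring; no unbiased
(non-candidate) TIS discovery; HARR and LTM are alternatives, not
combined; SQLite annotation caches are replaced by direct GTF parsing;
BLAST-based canonical mapping is replaced by containment matching with an
import hook. These either sit outside the method's defined scope or have
documented, conservative stand-ins.
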