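Package: ribodb
Title: Translated ORF Delineation and Proteoform Search-Space Construction
    from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms aligned ribosome-profiling (RIBO-seq) alignments from
    elongating (cycloheximide) and initiating (lactimidomycin/harringtonine)
    ribosomes into P-site occupancy profiles and genome-browser tracks,
    metagenic quality-control summaries, a set of translated transcript
    isoforms, called translation-initiation sites (annotated, upstream,
    downstream and near-cognate), and a non-redundant proteoform protein
    database in FASTA format suitable as an MS/MS search space. Sequence
    variants from an external caller and dbSNP-rescued read mismatches are
    folded into the translated sequences. A deterministic synthetic-fixture
    generator produces toy genomes, annotation, alignments and variant files
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
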