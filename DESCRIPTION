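Package: splicetope
Title: Splicing-Derived Neoantigen Burden from Splice-Junction Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the neoantigen burden contributed by aberrant mRNA
    splicing in bulk RNA-seq cohorts. Starting from splice-junction tables
    (STAR SJ.out.tab or BED-like .junc files), a reference annotation (GTF)
    and genome (FASTA), the package classifies junctions against the
    reference (annotated, novel annotated, cryptic), builds
    junction-modified transcripts by fusing flanking transcripts at each
    junction, locates and translates open reading frames, scores coding
    potential with an ORF-length/GC-content (LGC) model, derives MHC
    class-I binder peptide kmers under IC50, cross-group and
    reference-peptidome filtering, and summarises the result as per-gene
    and per-sample splicing antigenicity, optionally normalised by a
    pseudo tumor purity derived from ESTIMATE scores, together with
    differential agretopicity between tumor and normal splicing patterns.
    A seeded synthetic-cohort generator produces toy genomes, annotations,
    junction tables, count matrices, genotypes and proteomes so that every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
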