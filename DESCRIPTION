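Package: methylscan
Title: Sex-Differential Whole-Genome Bisulfite Methylome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis in species with fragmented genome assemblies: reading and
    filtering Bismark-style per-CpG cytosine reports, smoothing-based
    differentially methylated region (DMR) calling between tissues, DMR
    sharing classification and methylome clustering, GC- and length-matched
    bootstrap enrichment of DMRs in functional genomic categories,
    female-versus-male windowed methylation differences with metagene and
    TSS profiles, multi-evidence classification of unplaced scaffolds as
    X-linked (hypomethylation shift, sequencing-depth ratio, mapped-read
    proportion), and integration of region-level methylation with gene
    expression tables. Includes a seeded synthetic WGBS data generator with
    machine-readable ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
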