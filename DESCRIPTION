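Package: BnaGWAS
Title: Mixed-Model Association Mapping of Glucosinolate Content in
    Amphidiploid Rapeseed from GBS Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling analysis pipeline for
    genotyping-by-sequencing (GBS) panels of inbred Brassica napus lines:
    amphidiploid-aware SNP filtering (MAF, heterozygosity, missingness,
    per-call depth), variance-standardized genetic relationship matrix and
    principal components, centered-IBS kinship, per-environment compressed
    mixed-linear-model association scans with P3D variance components,
    cross-year significance combination via the Irwin-Hall distribution,
    linkage-disequilibrium decay and block-length estimation per subgenome,
    candidate-gene window annotation with a minimal coding-effect
    classifier, and flank-based SNP transfer between genome assemblies.
    Includes a calibrated synthetic-cohort generator (two-level
    Balding-Nichols structure, Markovian haplotype copying, GBS-like depth
    and missingness, planted QTLs) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'annotation.R'
    'crossmap.R'
    'filtering.R'
    'io.R'
    'irwinhall.R'
    'ld.R'
    'mlm.R'
    'phenotypes.R'
    'simulate.R'
    'pipeline.R'
    'plots.R'
    'simulate_annotation.R'
    'structure.R'
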