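Package: svnet
Title: Structural Variant Discovery and Population Genotyping from
    Whole-Genome Assembly Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An assembly-versus-assembly structural variant (SV) pipeline.
    Pairwise whole-genome alignments (PAF, MAF, AXT or MUMmer delta) of many
    genome assemblies against one reference are normalized to a common block
    representation, organized into collinear chains and hierarchical
    single-coverage nets, and mined for deletions, insertions, tandem
    duplications, inversions, translocations and complex loci as well as
    small indels and SNVs.  Per-sample calls are merged into a non-redundant
    population call set, every merged site is re-genotyped in every sample
    from local alignment context, and sites are annotated by formation
    mechanism (tandem expansion/contraction, transposable-element insertion,
    gene duplication).  The package ships SV simulators (reference-based,
    divergence-based and population-scale designs) that emit truth tables
    and exact truth alignments, plus benchmark metrics (recall/precision/F1,
    background subtraction, population completeness and per-sample
    genotyping accuracy), so the whole pipeline is verifiable end-to-end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
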