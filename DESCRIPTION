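Package: clonetrace
Title: Tracing Clonal Propagation Lineages from Somatic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Somatic-mutation-based lineage tracing for clonally propagated
    plants, modelled on whole-genome resequencing of grafted flowering-cherry
    clones against a haplotype-phased reference. Provides a four-stage somatic
    SNV filter cascade (biallelic, haplotype-specific homozygosity, replicate
    consistency, depth/quality), mutation-spectrum and sharing analysis,
    a simplified coding-effect classifier, clone clustering with
    cumulative-explained-variance cluster-number selection, ancestral-allele
    polarization against an outgroup panel, windowed log2-ratio copy-number
    deletion scanning with a Geary-Hinkley ratio test, and a synthetic
    clonal-propagation data generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR,
    vegan,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
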