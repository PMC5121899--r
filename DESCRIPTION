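Package: mirCurate
Title: Curation of Insect microRNA Complements from Small RNA-Seq with
    Dicer-1 Knockdown Support
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a microRNA
    annotation and curation pipeline for insect genomes. Starting from
    candidate hairpin loci and collapsed small RNA-seq libraries (control
    and Dicer-1-depleted), it applies expression filters (RPM
    normalisation, log2 fold change under Dicer-1 depletion,
    negative-control baselines), hairpin secondary-structure criteria
    (folding, free energy, mature/star pairing, 2-nt 3' overhangs), and
    homology rules to produce a curated set of conserved and novel
    miRNA genes grouped into seed families. Comparative layers add Dollo
    parsimony gain/loss reconstruction on a fixed species tree, genomic
    cluster detection, and seed-match target-count baselines against mock
    miRNAs. A seeded synthetic-data generator plants true hairpins and
    per-criterion decoy loci in a toy genome so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    ape,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, Annotation, Phylogenetics
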