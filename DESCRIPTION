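Package: crossmiR
Title: Plant miRNA Discovery from Small RNA Sequencing via a Surrogate
    Reference Genome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers plant microRNAs from small-RNA sequencing libraries of
    species without an assembled genome by mapping reads to the genome of a
    close relative (a surrogate reference). Implements adapter trimming and
    tag collapsing, exact multi-locus mapping, hairpin precursor folding with
    a deterministic weighted base-pair maximisation engine (thermodynamic
    engines pluggable), miRNA/miRNA* duplex validation against plant miRNA
    annotation criteria, a read-stack signature filter, homology rescue of
    conserved miRNAs against a known-miRNA catalogue, penalty-score target
    prediction with cleavage-site inference, and differential tag abundance
    testing with the Audic-Claverie exact test. A synthetic-data generator
    with machine-readable ground truth makes every stage testable without
    external downloads.
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
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, GeneRegulation, DifferentialExpression
RoxygenNote: 7.3.3
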