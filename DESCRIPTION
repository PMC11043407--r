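Package: casforge
Title: Mining and Characterization of Compact CRISPR-Cas9 Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, testable implementation of the computational workflow
    used to discover and characterize compact Cas9 nucleases from
    metagenome-assembled genomes: CRISPR array detection and cas1-cas2-cas9
    locus assembly with length/completeness/coverage filters, tracrRNA
    inference from anti-repeats and Rho-independent terminators with sgRNA
    scaffold construction and structural-module checks, PAM determination from
    randomized-library cleavage reads (position profiles, enrichment tables,
    degenerate consensus calling, cut-site geometry), and targeting-range and
    base-editor targetability estimation. Includes seeded synthetic-data
    generators with machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
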