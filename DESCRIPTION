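Package: orscreen
Title: Lineage-Restricted Odorant Receptor Curation and Heterologous
    Screen Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying lineage-restricted human odorant
    receptor (OR) genes and quantifying heterologous odorant screens.
    Covers open-reading-frame based functional/pseudogene curation of
    intronless OR genes, cross-species presence/absence screening by
    seed-and-extend local alignment with identity and coverage
    thresholds, pairwise amino-acid identity matrices, neighbor-joining
    phylogenies with bootstrap support, and quantification of 96-well
    CRE reporter plate screens (background double subtraction, fixed
    hit threshold, dose-response normalization, potency classes).
    Seeded simulators for OR-like genes, genomes with planted orthologs
    and reporter plates make every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
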