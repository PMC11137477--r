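Package: liftcompare
Title: Compare Gene Annotations Mapped Between Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares a reference genome annotation with the same annotation
    lifted onto a second assembly of the same or a closely related species.
    Feature identifiers shared between the two annotations establish the
    correspondence. Three analyses are provided: per-transcript sequence
    variants and their protein-level effects (classified by global
    Needleman-Wunsch alignment of transcript, CDS and protein sequences),
    gene-order synteny with ordinal dot plots and order edit distance, and
    paralog clustering at configurable identity/coverage thresholds to
    quantify gene copy-number gain and loss. A seedable synthetic fixture
    generator produces matched assembly/annotation pairs with known injected
    mutations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    rlang,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
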