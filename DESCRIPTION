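Package: cypscreen
Title: Bait-Gene Co-Expression Screening and Substrate-Inhibition
    Kinetics for Alkaloid Pathway Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative transcriptomics screen for candidate cytochrome
    P450 genes that co-express with a validated bait pathway gene across
    multiple de novo assemblies, in the style used to discover the
    para-para' C-C phenol-coupling enzyme of Amaryllidaceae alkaloid
    biosynthesis. Provides FASTA and expression-table input/output with
    assembly summary statistics (N50 and friends), a seeded synthetic-data
    generator that plants a bait-correlated P450 orthogroup among
    log-normal decoys, Smith-Waterman local-alignment homology search with
    Karlin-Altschul E-values, cytochrome P450 consensus-motif scanning and
    classification, HAYSTACK-style expression-model matching (correlation,
    background, fold-change and p-value cutoffs), cross-assembly homolog
    intersection with top-priority candidate ranking, and Michaelis-Menten
    / substrate-inhibition kinetics fitting with catalytic efficiency and
    assay mass bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
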