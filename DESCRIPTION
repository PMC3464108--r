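Package: pemscreen
Title: Colony-Size Genetic Interaction Scoring for PEM/SGA Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring pipeline for colony-size based genetic interaction
    screens in fission yeast (pombe epistasis mapper / synthetic genetic
    array designs). Implements two-step plate normalization (edge-ring
    correction to the plate middle mean, then scaling of all plates to the
    median middle mean), per-gene paired t statistics comparing double- to
    single-mutant colony sizes, Fisher combination of p-values across
    independent experiments, linkage-window exclusion of genes near query
    and marker loci, dual-threshold calling of synthetic sick and rescue
    interactions, hypergeometric gene-set overrepresentation of hit lists,
    and exact 2x2 contingency statistics for cytological phenotype
    comparisons. A synthetic screen generator with planted interactions
    provides fully specified ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
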