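Package: preimplantr
Title: Cross-Species Expression Profiling of Preimplantation Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-transition expression analysis for preimplantation
    embryo studies in human and mouse. Implements invariant-set
    normalisation and model-based (Li-Wong) probe-set summarisation for
    microarrays, ordinary and empirical-Bayes moderated t-tests between
    consecutive developmental stages with Benjamini-Hochberg FDR control,
    classification of genes into "Up", "Up-down" and "Down" expression
    profiles with cross-dataset intersection, a TaqMan qPCR -dCt pipeline
    with explicit undetected-value imputation policies, an RPKM
    fold-change filter for sequencing data, and an ortholog concordance
    classifier deciding whether a mouse ortholog follows its human
    counterpart or shows a maternal profile. A synthetic-data generator
    with planted profile archetypes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
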