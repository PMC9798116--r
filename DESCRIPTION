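Package: meripr
Title: Joint m6A/mRNA Epitranscriptomic Microarray Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel m6A epitranscriptomic
    (MeRIP-array) experiments in which immunoprecipitated (IP) and
    supernatant (Sup) RNA fractions are hybridised for each sample.
    Provides spike-in normalisation and QC-flag filtering, derivation of
    the three per-gene measures (m6A methylation level, m6A quantity and
    expression level), ordered-group differential screening with fold-change
    and significance coding, Venn-style gene-set intersections, a
    hierarchical five-evidence candidate-gene classifier, bench-side
    calculators (2^-dCt relative expression, colorimetric m6A ELISA), and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
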