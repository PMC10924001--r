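Package: methrecomb
Title: Methylome-Based Estimation and Prediction of Recombination Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate plant DNA methylation landscapes to meiotic
    recombination at the 100-kb window scale. Parses Bismark-style
    per-cytosine methylation reports, filters cytosines by methylation level
    and coverage, and counts retained cytosines per CG/CHG/CHH context per
    window; builds windowed recombination rates from parental-origin
    genotype matrices (nearest-marker imputation, Kosambi mapping function,
    map differencing) or from existing genetic maps; assembles smoothed
    consensus tables and context-recombination correlation reports; and
    predicts recombination rates from methylation features with extremely
    randomized trees under leave-one-chromosome-out and cross-dataset
    evaluation, including quartile-stratified correlations and additive
    per-feature attributions. A synthetic-data generator produces genomes,
    cytosine reports, and genotype matrices with known ground truth so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
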