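Package: devhourglass
Title: Evolutionary Simulation of Developmental Gene Networks and the
    Hourglass Pattern
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of layered developmental gene execution
    networks (DGENs) in an asexually reproducing population subject to gene
    deletion, duplication and regulatory rewiring, with regulatory-failure
    cascades and developmental-failure selection. Provides the hourglass
    score built on the normalized Mann-Kendall trend statistic, stage
    lethality, gene age and gene prevalence metrics, a transcriptome
    pipeline that identifies transitioning genes from staged expression
    matrices and computes stage-pair transcriptome age indices, and a
    synthetic-data generator with planted hourglass structure for end-to-end
    validation.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
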