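Package: microlens
Title: Transcriptome Cell-Identity Scoring and Micro-Lens Optical Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for two complementary analyses of
    stem-cell-derived lens models. First, compendium-based cell-identity
    scoring of bulk RNA-seq profiles: reads-per-million normalisation,
    top-k binary discretisation, ubiquity filtering, asymmetric binary
    dissimilarity with principal coordinates analysis, and tissue-specific
    marker-set enrichment by one-sided Fisher exact tests with
    Benjamini-Hochberg false discovery rate control. Second, focal-stack
    quantification of micro-lens function: central-region grey-level
    transmittance and focusing ratios from five-plane image stacks, with
    pooled two-sample t comparisons and dose-response summaries. A
    synthetic-data module generates expression compendia with planted
    tissue identities and simulated focal stacks so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
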