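Package: wareamd
Title: Wet Age-Related Macular Degeneration Risk Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the WARE (Wet AMD Risk Evaluation) model for exudative
    age-related macular degeneration: per-genotype odds ratios for the eight
    risk variants validated in the Italian population, normalization of raw
    odds ratios so that the frequency-weighted population-average risk equals
    one, multiplicative combination of genetic and non-genetic factors
    (smoking, family history), and exact enumeration of the risk distribution
    over all genotype combinations in the general population and among cases.
    Provides percentile and equal-risk-window summaries, low/high risk-zone
    classification, VCF and CSV subject-profile readers, a JSON risk report
    with density and pie-chart figures, a command-line interface, and seeded
    synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
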