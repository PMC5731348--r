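Package: deathpro
Title: Live/Dead Imaging Drug Screens: Segmentation, Dose-Response Metrics
    and Genomic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for confocal live/dead (Hoechst/propidium
    iodide) drug screens in 2D and organoid culture. Converts two-channel
    image stacks to maximum-intensity projections, segments dead-cell and
    all-cell areas by control-calibrated sequential local-mean thresholding,
    derives per-drug cell-death (LD50, AUCd) and proliferation-inhibition
    (AUCpi) metrics with ANOVA-gated log-logistic fits, and provides
    screen-level analytics (hierarchical clustering of response profiles,
    therapeutic indices, culture-type comparisons, replicate concordance).
    Also computes a modified HRD-LOH score from allele-specific copy-number
    segment tables and associates it with drug responses using linear-model
    R-squared and sampling-based false discovery rates. A synthetic-data
    module generates ground-truthed images, dose-response plates and segment
    tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
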