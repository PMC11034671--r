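Package: smoltomics
Title: Multi-Omics Integration of Liver Gene Regulation Across Salmon Smoltification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for integrating liver transcriptome, chromatin
    accessibility and DNA methylation dynamics across the parr-smolt transition
    of Atlantic salmon. Provides time-course differential expression with
    correlation-gated co-expression clustering, differential chromatin
    accessibility linked to nearest-TSS genes and tested for association with
    expression clusters, transcription-factor footprint occupancy scoring with
    environment (salinity/photoperiod) classification and binding-pattern
    enrichment, and RRBS differential methylation with a simulated random-pair
    correlation null. A synthetic-data generator with machine-readable planted
    ground truth drives recovery and calibration testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
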