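Package: dropvcn
Title: Vector Copy Number Quantification for Gene-Engineered T Cells by Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the integrated vector copy number (VCN) of
    CAR-T and TCR-T cell products from duplex droplet digital PCR (ddPCR) data.
    Includes a droplet-level simulator of duplex WPRE/TERT partitioning,
    amplitude thresholding and four-cluster droplet calling, Poisson inversion
    of droplet counts to absolute concentrations with confidence intervals,
    bulk VCN computation against a diploid reference gene, a Poisson-statistics
    adjustment of bulk VCN to the VCN of transduced cells together with
    per-cell VCN distributions, assay limit estimation (limit of blank, lower
    limits of detection and quantification), and assay validation statistics
    (dilution linearity, inter-assay coefficient of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
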