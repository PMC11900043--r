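Package: locusecho
Title: Genomic-Neighborhood Co-Expression and Position-Effect Analysis for Yeast Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the genomic neighborhood of focal genes
    in compact genomes such as Saccharomyces cerevisiae: ordered gene maps
    with signed distances and centromere/telomere orientation, focal-versus
    -flanking Pearson correlation profiles across condition blocks,
    exponential correlation-distance decay fitting, spotting-assay growth
    quantification with relative-growth statistics, 2^-ddCt qPCR relative
    quantification, and cross-species synteny anchoring. Includes a
    synthetic-data generator with known ground-truth parameters so every
    stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    MASS,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
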