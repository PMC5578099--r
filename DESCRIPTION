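Package: refstab
Title: Reference-Gene Selection and Expression-Stability Analysis for
    Circulating RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematically selecting and validating reference
    genes for normalizing circulating RNA measurements in whole blood.
    Implements replicate-based removal of unwanted variation (RUVs) for
    exon-level count matrices, coefficient-of-variation screening with
    percentile-based candidate selection and expression-range
    shortlisting, the geNorm expression-stability algorithm (M values,
    stepwise exclusion, normalization factors, pairwise variation
    V-series and the optimal-n rule), a model-based NormFinder-style
    stability estimator with intra- and inter-group variance components,
    and balanced two-subset concordance analysis of stability rankings.
    A seeded synthetic-data generator produces count matrices and Cq
    tables with known ground truth so the whole pipeline is testable
    without access to raw sequencing data.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
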