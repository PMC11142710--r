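Package: crabdiet
Title: Diet DNA Metabarcoding Analysis for Invasive European Green Crab
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for stomach-content DNA metabarcoding
    ("diet DNA") analysis of the invasive European green crab (Carcinus maenas).
    Translates tabular BLAST hits for COI amplicon sequence variants into a
    filtered per-crab prey-taxon dataset via a rule-based decision ledger
    (last-common-ancestor assignment, control/predator/non-target removal,
    species-plus-family collapse, native-status rules); computes diversity
    indices, the eDNA index, principal coordinates ordination and
    PERMANOVA/PERMDISP permutation tests of diet variation across sites;
    calibrates species-specific PCR amplification bias from mock communities of
    known composition to recover DNA template proportions; and estimates an
    "average diet" composition per site type with a zero-and-one-inflated
    Dirichlet compositional model. Ships a synthetic-data generator with known
    truth so every stage can be exercised end-to-end without sequencing data.
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
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
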