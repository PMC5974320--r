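Package: tomoloc
Title: Axial Localization Profiling of RNAs and Proteins from Tomographic
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of biomolecule localization along the animal-vegetal
    axis of the amphibian egg from tomographic (cryosection) RNA-seq and
    proteomic segment profiles. Provides qPCR-anchored size-factor
    normalization of section counts, rule-based localization classification
    of RNA and protein profiles with replicate consensus, homoeologue (.L/.S)
    concordance analysis, k-mer over-representation testing in 3'UTR sets,
    IUPAC and position-weight-matrix motif scanning with exact p-value
    thresholds, motif similarity clustering (UPGMA) with familial consensus
    profiles, and a fully seeded synthetic-data generator emulating the
    structure of such experiments for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
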