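Package: sedaprof
Title: Taxonomic Profiling of Sedimentary Ancient DNA from Archaeological Middens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling vertebrate and helminth DNA in shotgun-sequenced
    archaeological sediments. Implements lowest-common-ancestor (LCA) read
    assignment against a taxid-tagged organelle reference panel, read-level
    filters for degraded libraries (exact-duplicate removal, minimum length,
    DUST-style low-complexity score), 5-prime C-to-T deamination damage
    estimation for ancient-DNA authentication, per-layer faunal profiles with
    taxon collapsing and relative abundances, Bray-Curtis/NMDS ordination of
    layers, correlation of read counts with zooarchaeological NISP and biomass
    tables, and majority-rule consensus assembly with coverage depth. A
    synthetic-data module generates toy taxonomies, reference panels and
    damaged ancient-read libraries with known ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    generics,
    Rcpp,
    Biostrings,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
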