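Package: crustflux
Title: Sulfate Reduction Rates, Bioenergetics and Functional-Gene Diversity
    in Oceanic Crustal Fluids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of sulfate-reducing microbial activity in
    basaltic crustal borehole fluids. Computes sulfate reduction rates and
    minimum detection limits from 35S radiotracer incubation counts, apparent
    temperature optima from thermal-gradient experiments, Gibbs energies and
    catabolic energy densities of organotrophic sulfate reduction from fluid
    chemistry using an extended Debye-Huckel activity model and a bundled
    standard-state Gibbs energy table, qPCR-based dsrAB gene and cell
    abundances with cell-specific respiration rates, stoichiometric carbon
    mineralization fluxes, and dsrB clone-library diversity via
    average-neighbor OTU clustering with Chao1, Simpson evenness and
    non-parametric Shannon estimators. Includes a synthetic-data generator
    emulating every input so the full pipeline is testable without field
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
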