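Package: adtrace
Title: DNA Barcode Authentication and Microcalorimetric Screening of
    Animal-Derived Medicinal Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating animal-derived medicinal materials
    (horns, antlers, shells, scales) traded in processed form. Implements
    in-silico PCR cropping of mitochondrial COI barcode amplicons,
    alignment summary statistics (site classification, nucleotide
    diversity, base composition, haplotype counting, minimal diagnostic
    windows), Kimura two-parameter pairwise distances, intra/interspecific
    divergence partitioning with a barcoding-gap test, distance-based
    best-close-match species identification with leave-one-out validation,
    and neighbor-joining trees with bootstrap support and per-species
    monophyly checks. A companion thermokinetics component fits the
    exponential growth phase of isothermal microcalorimetry heat-flow
    power curves, extracts peak and total-heat parameters, computes
    inhibition ratios, and selects principal components of the parameter
    table. Includes seeded synthetic-data generators for species-clustered
    barcode sets under a two-parameter substitution process and for noisy
    exponential heat-flow curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
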