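Package: ferracet
Title: Electron-Balance Stoichiometry, Fe(III)-Reduction Kinetics and
    Heme-Motif Genome Surveys for Acetogen Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Fe(III) reduction by homoacetogenic
    bacteria. Implements the acetogenic reaction stoichiometry (ethanol
    and H2/CO2 routes to acetate) as a validated electron-equivalents
    ledger, electron-diversion accounting between control and
    iron-amended cultures, estimation of exponential-phase Fe(II)
    production rates and stationary-phase accumulation from culture
    time series, one-way ANOVA with Tukey's HSD across species and
    condition groups, heme-binding-motif (CxxCH and variants) scanning
    of proteomes with multiheme c-type cytochrome classification,
    assembly statistics, gene-panel presence screening by local
    alignment, and a synthetic-data module that generates
    electron-balanced culture time series and motif-planted proteomes
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Sequencing, Annotation, Microbiome
Config/testthat/edition: 3
RoxygenNote: 7.3.3
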