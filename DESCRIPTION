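Package: dualguide
Title: Design and Analysis of Dual-sgRNA CRISPRi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for compact dual-sgRNA CRISPR interference (CRISPRi)
    screens: empirical three-tier guide selection and dual-element library
    construction, integration-barcode (IBC) design under Hamming-distance
    and GC constraints, recombination-aware counting of paired-end screen
    sequencing reads, growth-phenotype (gamma) statistics with count
    filters and non-targeting-control centering, knockdown quantification
    from single-cell expression and flow-cytometry readouts, and a full
    screen simulator (library, lentiviral co-packaging with template
    switching, fitness-driven growth, multinomial sequencing) with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
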