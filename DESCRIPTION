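Package: offbase
Title: Off-Target Variant Analysis for Base-Editor Transgenic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genome-wide off-target
    assessment of CRISPR base editors in transgenic animals. Generates
    synthetic references, Mendelian trios, deaminase-signature variant sets
    and imperfect multi-caller outputs; implements the consensus-and-filter
    variant cascade (three-caller intersection, known-site and repeat-region
    masking, group-shared subtraction, trio de novo calling, RNA hard
    filters, DNA-RNA cross-filtering); and computes downstream statistics:
    twelve-type mutation spectra, trinucleotide context position weight
    matrices with information content, WCW motif enrichment, coding
    consequence annotation, shared-variant ratio matrices,
    expression-dependent SNV rate regression, expression-decile tables,
    phenotype threshold classification and amplicon editing efficiency.
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
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
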