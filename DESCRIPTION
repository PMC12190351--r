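Package: mhcdeconv
Title: Motif-Based HLA Immunopeptidome Deconvolution and Variant Epitope Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mass-spectrometry detected HLA ligandomes
    without relying on pretrained neural-network predictors. Trains
    transparent per-allele position-specific scoring matrices (PSSMs) with
    BLOSUM62 pseudocounts from eluted-ligand sets, calibrates scores to
    eluted-ligand-style percentile ranks against a background proteome,
    deconvolutes detected peptides to their best allele with class-specific
    rank cutoffs and strong/weak binder classes, screens protein point
    variants for mutant peptide windows that bind as strongly or more
    strongly than wildtype, and simulates synthetic ligandomes with known
    allele-of-origin truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
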