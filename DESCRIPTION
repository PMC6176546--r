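Package: crossdia
Title: Cross-Species DIA/SWATH Proteome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free cross-species comparison of DIA/SWATH
    proteomics data. Implements in-silico tryptic digestion and
    cross-species conserved-peptide indexing, peptide confidence and
    ambiguity filtering of long-format quantification reports,
    peptide-to-protein rollup with total-area and fast cyclic-loess
    normalization, iBAQ abundance estimation, empirical-Bayes moderated
    t-statistics with Benjamini-Hochberg false discovery rate control,
    gene-set chi-square enrichment, co-expression correlation and sample
    clustering quality control, and a synthetic multi-species data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
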