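Package: mitocontext
Title: Haplogroup-Context Analysis of Mitochondrial DNA Variant Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying deleterious combinations of individually
    common mitochondrial DNA variants. Computes haplogroup-conditional allele
    frequencies from population variant catalogs, a normalized pairwise
    cooccurrence statistic with an exact hypergeometric under-cooccurrence
    test, and a binomial transmission-skew test for pedigrees with a putative
    protective nuclear modifier. Also implements the quantitative cell-assay
    computations used to characterise such variant combinations: biexponential
    NADH fluorescence-lifetime (FLIM) fitting with fixed free/bound lifetimes,
    high-resolution respirometry state extraction with background subtraction,
    and flow-cytometry ratio metrics. A seeded synthetic-data generator
    produces catalogs with haplogroup linkage structure, pedigrees, photon
    decay stacks and oxygen-flux traces so every stage of the pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
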