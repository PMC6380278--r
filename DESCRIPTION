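Package: editqtl
Title: Discovery, Quantification and Genetic Mapping of RNA Editing Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for the analysis of adenosine-to-inosine (A-to-I) RNA
    editing in outbred mammalian populations. Candidate edit sites are
    discovered by subtracting DNA-called variants from RNA-called variants and
    curating them with quality, positional and cohort-level filters; editing
    proportions (phi) are quantified per animal and logit-transformed into
    mapping phenotypes; double-stranded pre-mRNA context is predicted by
    dot-plot scanning for inverted repeats; editing, expression and trait QTL
    are mapped with generalized least squares under a pedigree numerator
    relationship covariance; and cross-layer analyses test read-pair phase,
    allele complementarity and edQTL/eQTL cosegregation. A synthetic-data
    generator with pedigree gene-drop genotypes, planted inverted repeats and
    binomial read sampling makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
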