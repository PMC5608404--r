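Package: saltbarcode
Title: DNA Barcode Evaluation and Sampling Sufficiency for Habitat-Structured Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating DNA barcode loci and sampling strategies in
    widespread plant species whose intraspecific diversity is structured by
    habitat (e.g. inland populations versus coastal salt marshes). Implements
    Kimura 2-parameter distances with pairwise or complete site deletion,
    TaxonDNA-style best-close-match identification, tree-based species
    discrimination rates from support-annotated trees, DnaSP-style haplotype
    collapsing and habitat-stratified haplotype tables, principal coordinate
    analysis of distance matrices, Mann-Whitney comparison of intraspecific
    distance distributions, and a theta-resampling procedure that estimates
    the minimum sample size at which mean intraspecific distance stabilises.
    A Kimura-1980 sequence simulator provides ground-truth datasets for every
    stage, and a pipeline driver reproduces the full workflow from one seeded
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rlang,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
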