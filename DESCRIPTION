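Package: tcmconnect
Title: Connecting GWAS Disease Genes with Compound Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-pharmacology pipeline that links disease gene sets
    (GWAS-catalog associations grouped by MeSH Disease [C] level-3 terms and
    optionally expanded with high-confidence protein-protein interaction
    neighbors) to compound-induced expression signatures (fold-change
    differential expression against vehicle). Every compound-disease pair is
    scored by its observed gene-set overlap against a Monte-Carlo permutation
    null, summarised as a nominal p value, a Z-score, and a
    Benjamini-Hochberg q-value. Ships a fully seeded synthetic-data generator
    with planted signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
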