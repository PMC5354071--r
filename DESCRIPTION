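Package: palaeoprot
Title: Palaeoproteomic Authentication and Partitioned Protein Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taking peptide-spectrum matches from ancient bone
    proteomes through target-decoy filtering, deamidation-based endogeneity
    authentication with Gaussian-mixture clustering, consensus protein
    sequence reconstruction against a reference proteome, preparation of
    concatenated gene-partitioned amino-acid alignments (leucine/isoleucine
    collapse, telopeptide removal), and partitioned Dayhoff-model
    phylogenetic inference by maximum likelihood with bootstrap and by
    Bayesian MCMC with convergence diagnostics. Includes a synthetic-data
    generator that evolves protein sequences along a known tree and emulates
    tryptic PSM tables with age-dependent glutamine/asparagine deamidation,
    so the whole pipeline can be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
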