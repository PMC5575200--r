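Package: abcroutes
Title: Invasion-Route Inference from Barcode Haplotypes via Approximate
    Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the introduction history of invasive
    species from single-locus barcode data (mitochondrial CO1). Collapses
    aligned sequences into haplotype frequency tables, builds
    statistical-parsimony (TCS) haplotype networks, simulates pseudo-observed
    datasets under coalescent invasion scenarios with divergence, bottleneck
    and admixture events and an HKY mutation model with gamma rate
    heterogeneity, and performs Approximate Bayesian Computation scenario
    choice by rejection sampling with direct and multinomial
    logistic-regression posterior estimates, prior/scenario pre-evaluation by
    principal components, and posterior-based confidence in scenario choice.
    Ships the scenario configurations for a worldwide brown marmorated stink
    bug (Halyomorpha halys) analysis as worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
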