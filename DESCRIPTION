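Package: phylodiscord
Title: Coalescent Simulation, Concordance, and Comparative Analysis for
    Target-Capture Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for attributing cytonuclear discordance in phylogenomic
    data sets. Simulates gene trees under the multispecies coalescent on
    species trees and on species networks with reticulation inheritance
    probabilities; scores reference-tree clades against gene-tree sets and
    computes gene concordance factors; screens target-capture loci by
    bootstrap-support resolution and pairwise divergence; fits
    phylogenetically structured principal components and phylogenetic
    mixed models with likelihood-based R-squared and false-discovery-rate
    control; reconstructs continuous characters and geographic centroids
    under Brownian motion; and fits dispersal-extinction-cladogenesis
    models of discrete range evolution with stochastic mapping. Seeded
    synthetic-data generators reproduce the statistical structure of a
    montane plant radiation so every stage can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
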