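Package: commphylo
Title: Phylogenetic Community Structure and Its Sensitivity to the Input Phylogeny
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for community phylogenetics with an emphasis on how the
    input phylogeny shapes the answers. Computes mean pairwise distance (MPD)
    and mean nearest taxon distance (MNTD) with their standardized effect
    sizes (NRI, NTI) under an independent-swap null model; phylogenetic
    signal in continuous traits via Blomberg's K (permutation test) and
    Pagel's lambda (maximum likelihood with a likelihood-ratio test);
    congruence among distance matrices (CADM, Kendall's W) with a-posteriori
    Mantel tests on rank-transformed distances; tree perturbations
    (deep-branch stretching, tip shuffling) and origin-forced regression for
    comparing metrics across candidate phylogenies; and a synthetic-data
    generator (Yule trees, lambda-transformed Brownian traits, and
    clustered/overdispersed/random community assembly) so every stage can be
    validated on data with known structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
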