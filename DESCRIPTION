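Package: mygacomp
Title: Comparative Phylogenetics of Behavioral Niche Evolution in Mygalomorph Spiders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative analyses of discrete behavioral and
    morphological characters on genus-level phylogenies, motivated by the study of
    retreat-building behavior in mygalomorph spiders (trapdoor spiders, tarantulas and
    their kin). Provides matrix-representation-with-parsimony (MRP) supertree
    construction from overlapping input trees; ancestral state reconstruction of
    multistate characters by exact maximum parsimony and by maximum likelihood under
    Mk models (ER/SYM/ARD) with AICc selection across alternative branch-length sets;
    Gower dissimilarity and non-metric multidimensional scaling for discrete-character
    morphospaces; phylogenetically independent pairwise comparisons with randomized
    pairing schemes and a conservative max-p sign test; and maximum-likelihood tests
    of correlated evolution comparing twenty Markov models of paired binary characters
    (independent, x-dependent, y-dependent and interdependent rate structures, with
    hidden-rate-class counterparts of the independent models) by delta-AICc. A
    synthetic-data module simulates birth-death trees and character matrices with
    behavior-dependent rates, missing data and polymorphism, so that every stage of
    the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn (>= 2.10),
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vegan,
    withr,
    Matrix
Config/testthat/edition: 3
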