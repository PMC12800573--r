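Package: phylolink
Title: Phylogeny-Aware Linking of Gene Cluster Families and Metabolite
    Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical association of biosynthetic gene cluster families
    (GCFs) with metabolite families (MFs) across a strain phylogeny.
    Implements correlated-evolution tests for pairs of binary traits on a
    rooted tree (independent vs dependent continuous-time Markov models,
    likelihood ratio test, stationary-concordance direction statistic), a
    chi-squared comparator that ignores phylogeny, parsimony-based
    eligibility filtering, permutation controls and known-pair evaluation.
    Also provides comparative-genomics curation of BGC regions
    (supercluster splitting, core-gene reduction, domain-based family
    clustering), metabolite-family presence calling from MS feature
    tables, incidence-based rarefaction and extrapolation of GCF richness,
    and a seeded synthetic-data generator emulating the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
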