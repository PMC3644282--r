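Package: ctxnet
Title: Contextual Gene Set Interaction Networks with Condition-Specific Edges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns interaction networks among gene sets from trinary
    (UP/DOWN/NOCHANGE) expression data and detects which network edges are
    specific to a sample condition such as tissue type, tumour subtype or
    mutation status. Gene-set expression is summarized per sample by a
    majority-plus-hypergeometric rule; pairwise dependency likelihoods are
    estimated as undirected edge frequencies over many independent
    stochastic Bayesian-network structure searches (BDeu score, random
    restart hill climbing); condition specificity of each called edge is
    quantified by a leave-condition-out dependency-likelihood ratio with a
    permutation null. Includes a synchronous boolean-network simulator with
    perturbation clamping, a cholesterol-pathway model for the statins
    validation experiment, a planted-dependency synthetic data generator,
    and gene-set overlap and over-representation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
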