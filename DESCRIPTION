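Package: paleotip
Title: Tip-Dated Phylogenetics of Discrete Morphological Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One pipeline for phylogenetic analysis of discrete morphological
    character matrices with fossil taxa: maximum parsimony under equal and
    implied weights (random-addition search with SPR/TBR branch swapping,
    bootstrap support, ensemble consistency and retention indices), Mkv
    likelihood with gamma rate heterogeneity, Bayesian tip-dating under the
    fossilized birth-death tree prior with strict, independent-gamma (IGR)
    and autocorrelated lognormal (TK02) clock models, stepping-stone marginal
    likelihoods and Bayes factors, rogue-taxon detection and tree-set
    pruning, stratigraphic congruence indices (RCI, GER, MSM*) with
    permutation tests, ancestral-state reconstruction by parsimony mapping
    and stochastic character mapping with per-character model selection, and
    a forward simulator of fossilized birth-death trees and Mk-evolved
    matrices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
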