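Package: superfine
Title: Supertree Estimation by Matrix Representation and Strict Consensus Merger Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Supertree methods that combine a profile of unrooted source trees
    into a single tree on the union of their taxa. Implements the Baum-Ragan
    matrix encoding of a source-tree profile, matrix representation with
    parsimony (MRP) via a reversible Fitch parsimony engine and heuristic
    search, matrix representation with likelihood (MRL) under the symmetric
    two-state (CFN) model with discrete-gamma rate variation, the strict
    consensus merger (SCM), and SuperFine-style refinement of SCM polytomies
    with either base criterion. Also provides greedy (extended majority)
    consensus, topological error metrics (false negative and false positive
    rates, Robinson-Foulds, Sum-FN), p-ECR tree neighborhoods with a
    score-versus-error rank-correlation protocol, and a synthetic generator
    of clade-plus-scaffold source-tree profiles for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
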