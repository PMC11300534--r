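Package: sbnsupertree
Title: Supertree Distributions over Rooted Tree Topologies via Subsplit
    Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds probability distributions over rooted, bifurcating
    phylogenetic tree topologies on a union taxon set from posterior tree
    distributions given on overlapping taxon subsets.  Tree distributions
    are parameterized as subsplit Bayesian networks (clade-conditional or
    subsplit-conditional), for which the package provides exact restriction
    to taxon subsets, closed-form KL divergences, mutual supertree-support
    construction from reference supports, and gradient descent on the sum
    of restricted KL divergences with analytic softmax gradients.  A
    synthetic-fixture generator (coalescent topology sampling, random SBNs,
    leave-one-taxon-out reference designs) supports simulation studies and
    end-to-end testing without external tree samplers.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
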