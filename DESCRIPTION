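Package: hostnet
Title: Structure of Host-Use Bipartite Networks Under Alternative
    Diversification Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ask whether the structure of a binary
    herbivore-by-host-plant interaction network carries the signature of the
    diversification process that built it.  Simulates interaction networks on
    a fixed guide phylogeny under adaptive-radiation, host-repertoire
    variability, random and uniform-evolution generative rules; measures
    nestedness (NODF) and bipartite (Barber) modularity, the latter maximised
    by simulated annealing; tests both against a degree-proportional cell
    null model with permutation p-values and z-scores; classifies taxa into
    structural roles from within-module degree and among-module connectivity;
    scores the importance of every pair of host taxa by deletion; and tests
    the phylogenetic diversity (Faith's PD) of module memberships against a
    tip-label-shuffle null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
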