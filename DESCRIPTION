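Package: saccharify
Title: Stochastic Simulation and Sensitivity Analysis of Lignocellulose Saccharification
Version: 0.1.0
Authors@R: person("saccharify", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Coarse-grained stochastic (Gillespie) simulation of the enzymatic
    saccharification of a lignocellulose microfibril by a four-enzyme cocktail
    (endoglucanase, cellobiohydrolase, beta-glucosidase, xylanase), including
    cellulose/hemicellulose crystallinity, end-product inhibition of cellulases
    and non-productive enzyme adsorption on lignin. Ships a closed-form
    characteristic-time framework identifying the time-limiting enzymatic step,
    a variance-based (Sobol) global sensitivity pipeline with Saltelli-style
    cross sampling and Jansen total-order estimation, synthetic reference-curve
    fixtures, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
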