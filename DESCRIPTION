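Package: latchnet
Title: Latching Attractor Network Simulations of Semantic Priming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a two-layer (lexical and semantic) attractor neural
    network with sparse Hopfield-style covariance connectivity, continuous-time
    rate dynamics, temporally correlated noise, and Tsodyks-Markram short-term
    synaptic depression. Depression destabilizes semantic attractors and
    produces latching dynamics (spontaneous hopping between correlated memory
    patterns). The package builds the correlated concept patterns, runs
    simulated semantic-priming experiments at short and long stimulus onset
    asynchrony for a control and an elevated-utilization ("schizophrenic")
    condition, and computes priming effects, attractor-transition statistics,
    and the statistical spreading-activation wave.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
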