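Package: thetasweeps
Title: Behavior-Dependent Theta Sweeps in a Continuous Attractor Network of Place Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent continuous-attractor network of hippocampal
    place cells with short-term synaptic facilitation and depression that
    internally generates theta sequences, and anchors them to positions on a
    linear track through a theta-gated Hebbian rule on weakly spatially tuned
    inputs. Provides the analysis suite for the resulting activity:
    place-field extraction from activation maps, phase-precession slopes by
    orthogonal distance regression, instantaneous-speed invariance ratios,
    place-field density, population-vector decoding by template correlation,
    and per-theta-cycle sweep metrics (look-behind, look-ahead, length), plus
    a reproducible multi-run experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
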