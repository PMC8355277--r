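Package: mpfcgradient
Title: Functional-Gradient Analyses of Trial-Aligned Spike Trains in Medial Prefrontal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for detecting a ventrodorsal functional gradient
    across four medial-prefrontal areas recorded during two-offer risky
    choice: per-neuron value selectivity and encoding latency, population
    signatures of value comparison (feature integration, attentional
    alignment, mutual inhibition), intrinsic-timescale estimation from
    spike-count autocorrelation, pseudo-population cross-validated decoding
    with shuffle nulls, and cross-area gradient-order rank statistics.
    Includes a doubly-stochastic (Ornstein-Uhlenbeck rate) Poisson spike
    simulator that emulates the task so the full pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm,
    MASS,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
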