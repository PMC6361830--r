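Package: timecellr
Title: Chain Model of Hippocampal Time Cells with Scalar Timing Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a feedforward chain of spikeless integrate-and-fire
    "time cells" whose delayed firing is governed by a slowly inactivating
    D-type potassium current under linearly accumulating synaptic inhibition.
    The package provides the single-cell and network dynamical core (fixed-step
    integration in C++), stochastic ingredients (trial-wise normally perturbed
    maximal conductances and Poisson presynaptic bombardment), runnable
    experiment protocols (single-cell delayed firing, chain wave, multi-trial
    statistics, parameter sweeps), and the statistics layer for interval-timing
    analyses: per-cell spike-time means, standard deviations and coefficients
    of variation, mean-normalized spike-time histograms with superposition
    tests, and analytic/Monte-Carlo null models for sums of independent
    inter-spike intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
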