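Package: rhythmogen
Title: Generative Models of Categorical Rhythm in Spiking Neurons and Cricket Stridulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two minimal generative models of rhythmic event
    production -- a leaky integrate-and-fire neuron with alpha-shaped
    synaptic currents driven by external spike trains, and a phase-response
    -curve model of cricket stridulation with a tunable relaxation rate --
    and quantifies the rhythmic structure of the resulting event sequences.
    Provides inter-onset intervals, rhythm ratios r = i_k/(i_k + i_{k+1}),
    Gaussian kernel density estimates, weighted on-/off-integer fractions
    for seven small-integer ratio categories, and a spacing-based
    (Ebrahimi) differential entropy estimator with explicit handling of
    degenerate (isochronous) sequences. Seeded two-dimensional parameter
    sweeps reproduce three computational experiments: random (Poisson)
    forcing, isochronous forcing across input-frequency ratios, and a
    connection-strength sweep, yielding entropy and ratio-category
    heatmaps that exhibit mode locking and Arnold-tongue-like structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
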