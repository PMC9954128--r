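Package: neftools
Title: Spiking Neural Network Synthesis with Spatiotemporal Tuning Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional spiking neural networks by assigning
    (spatio)temporal tuning curves to leaky integrate-and-fire populations
    and solving regularized least-squares problems for the synaptic weights
    that realize desired transformations and dynamics.  Includes the
    Legendre Delay Network and Modified Fourier temporal bases and the time
    cell networks they induce, online error-driven learning (the prescribed
    error sensitivity rule and a learned Legendre multi-step predictor),
    Spatial Semantic Pointer vector-symbolic encodings of continuous
    variables with binding algebra and cognitive-map queries, grid, place,
    border and object-vector cell models, oscillator-based path integration,
    temporal trajectory integration, and quasi-probability kernel density
    estimation, together with a time-stepped network simulator and
    seed-deterministic synthetic data generators for every experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
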