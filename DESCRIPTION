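Package: twinbrain
Title: Connectome-Conditioned Digital Twin Models of Task Behavior and BOLD Dynamics
Version: 0.1.0
Authors@R:
    person("Twinbrain", "Developers", email = "twinbrain@example.org", role = c("aut", "cre"))
Description: Builds individualized generative models of task behavior and
    regional BOLD time series from resting-state functional connectomes.
    A hypernetwork (multilayer perceptron with Mish activations) maps a
    Fisher-z vectorized resting-state functional connectivity matrix to the
    full parameter set of a per-participant vanilla recurrent network that
    converts sensory and task-condition inputs into next-step button-press
    probabilities and regional BOLD predictions. Includes a synthetic cohort
    generator with planted affective and cognitive traits, fMRI-style
    preprocessing (Fisher-z connectomes, cubic resampling, train-split
    normalization), general linear model analysis with a Glover hemodynamic
    response function and discrete cosine drift basis, partial least squares
    derivation of intervention directions over network parameters, SmoothGrad
    attribution of connectome edges, and in-silico weight-perturbation
    intervention simulation with standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
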