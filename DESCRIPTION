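Package: specdcm
Title: Spectral Dynamic Causal Modelling of Default-Mode-Network EEG with
    Empirical Bayes Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a biophysical generative model (a four-source default mode
    network of Jansen-Rit style neural masses coupled by forward, backward and
    lateral connections) to resting-EEG cross-spectral densities by variational
    Laplace, takes subject-level posteriors over extrinsic coupling strengths
    to the group level with parametric empirical Bayes, prunes and averages
    models by analytic Bayesian model reduction, and classifies conscious state
    from directed connection strengths with leave-one-subject-out and
    leave-one-state-out cross-validation. Includes a synthetic-cohort generator
    emulating a disorders-of-consciousness study design, a stochastic
    time-domain simulator used as an independent oracle for the linearized
    spectral predictions, and Welch cross-spectral estimation for multichannel
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
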