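Package: sleepda
Title: Data Assimilation for Sleep-Wake Regulatory Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for firing-rate/neurotransmitter models of the mammalian
    sleep-wake regulatory network (a mutually inhibitory wake/sleep flip-flop with
    REM-active cholinergic populations, homeostatic sleep drive, stochastic
    thalamic input, and an optional circadian extension with a suprachiasmatic
    nucleus cell group), together with an unscented Kalman filter for
    reconstructing hidden variables from sparse noisy observations. Includes an
    empirical observability coefficient for ranking which variables are worth
    measuring, covariance-inflation tuning guided by that ranking, multiple
    shooting estimation and windowed tracking of model parameters, and
    assimilation of discretized hypnograms through state-conditioned
    pseudo-observations.
License: MIT
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
    optparse
Config/testthat/edition: 3
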