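Package: ensembleflow
Title: State-Space Reconstruction and Attractor Detection for Neural Ensemble Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs high-dimensional state spaces from multi-unit spike
    recordings by combining delay-coordinate embedding of smoothed firing rates
    with an implicit multinomial (polynomial-kernel) expansion, and analyzes the
    resulting spaces with regularized kernel Fisher discriminant analysis and
    kernel PCA. Provides cross-trial prediction statistics (segregation error,
    predicted segregation error, Kullback-Leibler epoch divergence),
    autocorrelation-preserving block-bootstrap surrogates, trajectory-flow
    convergence measures (likelihood-velocity slopes, escape/trapping-region
    quantification), correlation-dimension diagnostics, and a synthetic
    multistable-ensemble spike simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
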