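Package: epinet
Title: Epileptogenic Network Characterization from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes an epileptogenic network from resting multichannel
    EEG in three stages: constrained blind source extraction (Functional
    Source Separation, a FastICA-type negentropy contrast augmented with a
    spike-locked power constraint and optimized by simulated annealing),
    signal-complexity quantification of the extracted source time courses by
    the Higuchi fractal dimension in non-overlapping windows, and directed
    spectral connectivity between the epileptogenic source and the residual
    brain network by the Directed Transfer Function over multivariate
    autoregressive fits of 20-s segments. Includes a ground-truthed
    synthetic-EEG generator (spike-and-wave transients embedded through a
    fixed scalp topography into ongoing background activity) so every stage
    is testable without patient data, and an orchestrated four-condition
    pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
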