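Package: linident
Title: Parameter Correlations and Identifiability in Partially Observed
    Linear Dynamic Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Symbolic-numeric identifiability analysis for linear
    time-invariant state-space models with named rate parameters, as used
    for compartment models in systems biology and pharmacokinetics.
    Detects pairwise and higher-order parameter correlations from the
    Laplace-domain output sensitivity matrix, classifies them as
    structurally or practically non-identifiable with explicit dependence
    on the initial condition and constant controls, derives identifiable
    parameter combinations by solving the invariance condition with a
    polynomial ansatz, computes the minimal number of experiments needed to
    remedy practical non-identifiability, and verifies every verdict by
    noise-free simulation and repeated least-squares refitting.  Includes
    an exact sparse multivariate polynomial and rational-function kernel,
    five classic compartment-model fixtures (including an insulin receptor
    trafficking model), and a random model generator for property-based
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
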