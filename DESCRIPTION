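Package: pgme
Title: Phase-Dependent Generalized Multiscale Entropy for Trunk-Acceleration Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies phase-dependent irregularity of daily-life walking from
    tri-axial trunk acceleration. Implements delay-space reconstruction of the
    gait dynamics with an average-mutual-information lag, multivariate
    empirical mode decomposition (MEMD) into intrinsic mode functions,
    generalized (Tsallis q-order) sample entropy evaluated within step-cycle
    phase windows, and assembly of the resulting scale-by-phase-by-q entropy
    tensor (PGME) per epoch and per subject. Also provides a conventional
    trunk-acceleration gait-feature battery (stride regularity, harmonic
    ratio, index of harmonicity, spectral features, low-frequency percentage,
    Lyapunov exponents), a matched-pair PLS discriminant fall-prediction
    pipeline with NIPALS, target-projection feature ranking, backward feature
    elimination, bootstrap confidence intervals and AICc model comparison, and
    a seeded synthetic gait generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
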