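Package: resphase
Title: Respiration Phase-Resolved Analysis of Perception and Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the respiratory cycle modulates perception
    and neural population dynamics. Covers respiratory phase extraction from
    belt recordings (z-scoring with sigh clipping, prominence-based extrema,
    piecewise-linear phase), pupillometry preprocessing, a QUEST adaptive
    staircase with cumulative-Gaussian psychometric fitting and moving-window
    respiration phase-resolved threshold profiles, circular statistics
    (Rayleigh, Hodges-Ajne, circular-linear correlation, sine/cosine phase
    regression), DPSS multitaper spectra with derivative whitening and
    phase-binned power, nonparametric blockwise spectral Granger causality via
    Wilson factorization with the directed asymmetry index, cluster-based
    permutation inference and Gaussian-copula mutual information, and a
    synthetic-data generator with known ground truth so that every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
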