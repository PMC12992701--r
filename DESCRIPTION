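Package: dynfa
Title: Dynamic Factor Analysis for Sparse and Irregular Longitudinal Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian dynamic factor analysis for longitudinal biomarker panels
    that are sparsely and irregularly sampled across subjects. Observed
    biomarkers load sparsely (point-mass mixture priors) onto a small number of
    latent factor trajectories which follow a multi-output Gaussian process
    built by kernel convolution, allowing non-zero cross-correlations between
    factors, constant non-zero factor means and a roughness penalty on the
    kernel decay parameters. Hyperparameters are estimated by a stochastic EM
    algorithm; all remaining unknowns by a block Gibbs sampler. Includes a
    synthetic-data generator, signed-permutation alignment of posterior draws,
    cross-validation for the roughness penalty, and posterior predictive
    trajectory reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
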