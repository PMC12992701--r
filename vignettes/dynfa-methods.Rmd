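---
title: "Penalized dynamic factor analysis for sparse irregular longitudinal panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized dynamic factor analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfa)
```

## The problem

Longitudinal biomarker panels from clinical studies are often *sparse and
irregular*: each subject contributes only a handful of visits (often just
two), visit times differ across subjects, and tens of biomarkers are
measured at each visit. Scientific interest usually lies one level above the
individual biomarker — in a small number of latent processes ("pathways")
whose activity drives groups of biomarkers over time, and which may interact
with one another.

`dynfa` fits a Bayesian dynamic factor analysis model built for exactly this
regime. Three ingredients distinguish it from classical factor analysis:

1. **Sparse loadings.** Each biomarker loads on each factor through a
   point-mass mixture (spike-and-slab) prior, so most loadings are exactly
   zero and factor membership needs no post-hoc thresholding.
2. **Correlated smooth factor trajectories.** The vector of factor
   trajectories follows a multi-output Gaussian process (MOGP) constructed
   by kernel convolution, which yields a valid cross-covariance between
   factors — factors are not forced to be independent.
3. **Regularization for sparse sampling.** Gaussian processes overfit badly
   when a subject has two or three observations. The package counters this
   with (a) a roughness penalty on the kernel decay parameters, and (b)
   constant non-zero factor mean functions estimated from the data.

## The model

For subject $i$, biomarker $g$, visit $j$ at time $t_{ij}$:

$$x_{ijg} = \mu_{ig} + \sum_{a=1}^{k} l_{ga}\, y_{ija} + e_{ijg}, \qquad
  e_{ijg} \sim N(0, \phi_g^2),$$

with subject-biomarker intercepts $\mu_{ig} \sim N(\mu_g, \sigma_g^2)$
($\mu_g$ fixed at the empirical mean of biomarker $g$), loadings
$l_{ga} = Z_{ga} A_{ga}$ where

$$Z_{ga} \sim \mathrm{Bern}(\pi_a),\quad \pi_a \sim \mathrm{Beta}(c_0, d_0),
\qquad A_{ga} \sim N(0, \rho_a^2),\quad
\rho_a^2 \sim \mathrm{IG}(c_1, d_1),$$

and $\sigma_g^2 \sim \mathrm{IG}(c_2, d_2)$,
$\phi_g^2 \sim \mathrm{IG}(c_3, d_3)$.

### The convolution-process MOGP

Each factor trajectory decomposes as
$y_a(t) = \xi_a(t) + \eta_a(t) + \epsilon_a(t)$, where
$\xi_a = h_{a0} * \tau_0$ convolves a white-noise base process *shared by
all factors*, $\eta_a = h_{a1} * \tau_a$ convolves a factor-specific one,
and $\epsilon_a(t) \sim N(0, \psi^2)$ is a nugget. All smoothing kernels are
Gaussian, $h(t) = v\, e^{-B t^2/2}$ with $B > 0$. Convolving two such
kernels against a shared white-noise process gives the closed form used
throughout the package:

$$\int h_a(dt + u)\, h_b(u)\, du
  = v_a v_b \sqrt{\frac{2\pi}{B_a + B_b}}
    \exp\!\left\{-\frac{B_a B_b\, dt^2}{2\,(B_a + B_b)}\right\}.$$

Hence the auto-covariance of factor $a$ at lag $dt$ is

$$C_{aa}(dt) = v_{a0}^2 \sqrt{\pi / B_{a0}}\, e^{-B_{a0} dt^2/4}
            + v_{a1}^2 \sqrt{\pi / B_{a1}}\, e^{-B_{a1} dt^2/4}
            + \delta_{dt}\, \psi^2,$$

and the cross-covariance between factors $a \ne b$ (induced by the shared
base process only) is
$C_{ab}(dt) = v_{a0} v_{b0} \sqrt{2\pi/(B_{a0}+B_{b0})}\,
e^{-B_{a0}B_{b0} dt^2 / (2(B_{a0}+B_{b0}))}$, giving the constant-in-time
cross-correlation
$\rho_{ab} = C_{ab}(0) / \sqrt{C_{aa}(0)\, C_{bb}(0)}$.

These closed forms are *locked to a quadrature oracle* in the test suite:
for random parameter/lag tuples the analytic expressions must agree with
adaptive numerical integration of the defining convolution to $10^{-8}$.
This makes the kernel convention — in particular the $\sqrt{\pi/B}$
prefactor and the $B\,dt^2/4$ exponent — verifiable rather than a matter of
transcription.

Larger $B$ means faster-decaying correlation, i.e. rougher trajectories.
The fitting objective therefore subtracts the roughness penalty
$\lambda \sum_a (B_{a0} + B_{a1})$.

### Identifiability

Two non-identifiabilities require care:

* **Scale.** The factor covariance scale trades off against the loadings.
  The package constrains every factor's stationary variance to 1
  ($C_{aa}(0) = 1$); `normalize_unit_variance()` rescales amplitudes,
  nugget *and constant means* by $1/s_a$ and reports the scales $s_a$ so
  callers can absorb them into loading columns. A consequence worth noting:
  although the nugget $\psi^2$ is specified as shared across factors, the
  per-factor rescaling makes the *effective* nugget factor-specific; the
  package stores it per factor.
* **Signed permutations.** Permuting factor labels and flipping factor
  signs jointly in (loading columns, score rows) leaves the observation
  likelihood unchanged — $2^k k!$ equivalent representations. Posterior
  draws are re-aligned (`align_draws()`) to a reference draw (the retained
  draw with the highest complete-data log density) by exhaustive search
  over signed permutations minimizing the mean absolute loading difference;
  for simulation scoring, `align_to_truth()` aligns estimated
  cross-correlations to the generating truth the same way. Note that a
  sign flip negates cross-covariances, so only the *observation* likelihood
  is exactly invariant; alignment is a summarization device, applied before
  any posterior summary is computed.

## Inference

### Block Gibbs sampler

Conditional on fixed MOGP hyperparameters, all full conditionals are
available by conjugacy. One systematic scan updates, in fixed order (fixed
for reproducibility): the subject-biomarker means and the two variance
families; the loadings machinery; and each subject's factor scores. Design
choices:

* **Collapsed loading update.** For each $(g, a)$, the inclusion indicator
  $Z_{ga}$ is drawn with the slab coefficient $A_{ga}$ integrated out
  analytically (a Gaussian integral), then $A_{ga}$ is drawn from its
  conditional (the prior when $Z_{ga} = 0$). The collapsed form avoids the
  absorbing state of naive two-step updates: odds are computed in log space.
  $A$ stays fully instantiated when $Z_{ga}=0$, and the $\rho_a^2$ update
  uses all $A_{ga}$ (documented so users can reason about the variant that
  uses only included rows).
* **Two-stage factor block.** Scores live on the *augmented grid* — the
  union $t$ of all visit times — so the M-step below sees a common grid.
  Stage 1 draws the scores at the subject's own visit times from their MVN
  full conditional (prior restricted to those times + Gaussian likelihood);
  stage 2 draws the remaining grid times from the MOGP conditional given
  stage 1. Subjects sharing a visit pattern share every pattern-level matrix
  factorization, so both stages are vectorized across subjects; under a
  regular design there is a single pattern.
* A subject with no observations is drawn from the MOGP prior; each chain's
  seed derives deterministically from the master seed.

Every conditional is checked in the tests against an independent brute-force
oracle (numerical integration for the collapsed inclusion probability,
direct joint-Gaussian conditioning for the block update), and the sampler as
a whole passes a Geweke-style joint-distribution check on a tiny model
(forward simulation versus successive-conditional simulation).

### Stochastic EM for the hyperparameters

The marginal likelihood of the panel integrates over all latent variables
and is intractable. The package estimates $(\Theta, C)$ — kernel parameters
and constant means — by stochastic EM:

* **S-step.** Run the Gibbs sampler at the current estimates
  (`s_chain_len` scans, default 500, 20% burn-in; the chain state is
  carried across iterations), then take **one** draw of the augmented
  scores, uniformly at random from the post-burn-in scans.
* **M-step.** Maximize the penalized augmented-grid score log-likelihood
  $\sum_i \ln \mathrm{MVN}(\mathrm{vec}(Y_{i,\mathrm{aug}}^T) \mid
  C_{\mathrm{aug}}, \Sigma(\Theta, t)) - \lambda \sum_a (B_{a0}+B_{a1})$
  by L-BFGS-B. The covariance is built and factorized once per objective
  evaluation (common grid, shared across subjects).

The iterates form a homogeneous Markov chain; the estimator is the average
of the last $m$ iterates (default 50 of 200) *in the transformed parameter
space*, then back-transformed.

**Parameterization.** The unit-variance constraint is built into the
optimizer's coordinates. Per factor the free parameters are
$\beta_0, \beta_1 \in \mathbb{R}$ and $\log B_0, \log B_1$, with stationary
variance shares
$(w_\xi, w_\eta, w_{\mathrm{nug}}) = (\beta_0^2, \beta_1^2, 1) /
(1 + \beta_0^2 + \beta_1^2)$ and amplitudes
$v_0 = \mathrm{sign}(\beta_0)\sqrt{w_\xi \sqrt{B_0/\pi}}$,
$v_1 = \sqrt{w_\eta \sqrt{B_1/\pi}}$, nugget $w_{\mathrm{nug}}$. The
diagonal is exactly 1 by construction, $\mathrm{sign}(\beta_0)$ carries the
sign of the shared-process amplitude (so negative cross-correlations are
reachable), and $\beta_1$'s sign is irrelevant and canonicalized positive so
that trailing averages cannot cancel. The constant means $c_a$ have a
closed-form GLS profile solution and are profiled out inside the objective.
$\log B$ is bounded in $[-6, 10]$ to keep the covariance numerically sane.

**Initialization.** The latent-state initialization matters more than is
usual for MCMC, because the factor model with correlated scores and sparse
loadings has a nearly observationally equivalent competitor: orthogonalized
scores with denser loadings. A sampler started near — or pushed toward —
the dense representation can stay there for many scans, dragging the StEM
cross-correlation estimate toward zero, and the effect strengthens with
$n$ as the posterior modes sharpen. `dynfa` therefore initializes along a
chain of standard factor-analytic steps, each addressing one failure mode
observed when it is omitted:

1. truncated SVD of the within-subject-centered data, followed by a
   **promax (oblique) rotation** — with cross-correlated factors the sparse
   loading axes are an oblique, not orthogonal, rotation of the SVD basis,
   so varimax alone systematically mixes them;
2. a few **alternating least-squares passes with per-column hard
   thresholding**, whose regression scores on the sparsified loadings carry
   the cross-correlation that orthogonal SVD scores cannot express;
3. **sign anchoring**: factor signs are flipped so initial score
   cross-correlations against factor 1 are non-negative, removing a sign
   conflict with the hyperparameter start;
4. $\Theta^{(0)}$: a scale-aware neutral kernel start ($B$ such that
   correlation halves at a quarter of the observed time span, equal
   variance shares, zero means), immediately refined by **one M-step on the
   initial scores** so that the score prior starts at the correlation and
   smoothness the initial state itself implies. Without this, the prior at
   its neutral correlation pulls the early chain away from the initial
   sparse representation.

The spike-and-slab prior then refines factor membership during sampling.
A user-supplied `theta_init` bypasses step 4.

### Choosing the penalty $\lambda$

`cross_validate_lambda()` selects $\lambda$ on a log-spaced grid (default
$\ln\lambda \in [-4, 4]$ step $0.5$: 17 candidates from 0.02 to 54.60) by
subject-level cross-validation: subjects are partitioned into $l$ folds
(default 5; the fold count is a package default, chosen as standard
practice); per fold, hyperparameters are fitted on the training subjects
only, one randomly chosen visit of each test subject is held out, the Gibbs
sampler runs on the remaining data under the frozen hyperparameters, and
held-out biomarker values are predicted by posterior medians. What the
prediction conditions on was a genuinely open design point: predicting from
the prior mean alone would make $\lambda$ nearly irrelevant, so the package
conditions on the test subject's *other* visits (leave-one-time-out), which
matches how the model is used. Test subjects with a single visit are
skipped with a warning. Per-fold StEM settings are typically scaled down
relative to the final fit; the CV result records fold assignments and
held-out times.

## The synthetic-data generator

`simulate_panel()` reproduces two study designs and ships the ground truth
with every dataset:

* `regular_sim_config(n)`: the benchmark regular design — $k = 4$ factors,
  $p = 100$ biomarkers, $q_i = 8$ common times, each factor expected to
  regulate 10% of biomarkers ($c_0 = 0.1p$, $d_0 = 0.9p$, so
  $E\pi_a = 0.1$), non-zero loadings $\sim N(4, 1)$, grand means equally
  spaced in $[4, 16]$, $\sigma_g = \phi_g = 0.5$, zero factor means, and
  factor scores drawn iid over time from a correlation matrix with non-zero
  off-diagonals. The default truth correlation uses pairwise values
  $\{0.6, 0.3, 0.1, 0.3, 0.1, 0.1\}$ (positive definite, configurable);
  the common times are $0, \dots, 7$ (only time *differences* matter to the
  stationary model, so the placement is a convention).
* `irregular_sim_config()`: a sparse clinical design — $n = 101$ subjects,
  $p = 35$ biomarkers, per-subject visit counts in $\{2,\dots,5\}$ with
  about half the subjects at 2 visits, times drawn without replacement from
  the 50 integer days $0..49$.

Scores can alternatively be drawn from a convolution-process MOGP
(`score_mode = "mogp"`) for temporally smooth trajectories; the iid mode
matches the benchmark's fixed-covariance description, and both are exposed
because the benchmark's time structure admits either reading.

**What the generator does and does not emulate.** It reproduces sparsity
patterns, visit-count distributions, noise scales and factor
cross-correlation; it does not emulate real metabolite marginal
distributions, measurement batch effects, informative visit timing, or
dropout/death censoring. Passing recovery tests on these panels therefore
demonstrates correctness of the estimation machinery under the model, not
robustness to the ways real data violate it.

## Numerical choices

* **PSD tolerance/jitter.** If a Cholesky factorization fails, one round of
  jitter ($10^{-8} \times$ mean diagonal) is added; a second failure is a
  hard error naming the context.
* **Ties in reference-grid coarsening** (`map_to_reference_grid()`): each
  observed time maps to the nearest reference time, ties broken toward the
  earlier one; when two visits of a subject collide on one reference time
  the earlier visit is kept and the drop is reported. The rule is isolated
  behind this single operation and diagnostics quantify how close the
  mapping is to a constant per-subject shift.
* **Age regression-out** (`regress_out_age()`): biomarker-specific OLS of
  all observations on intercept + subject age; residuals are exactly
  uncorrelated with age by construction.
* **M-step failures** return the best evaluated point with a flag; a failed
  M-step inside StEM reuses the previous estimate and flags the iteration.
* **Degenerate inputs:** subjects with one visit are accepted with a
  warning; a subject with no observations draws its scores from the prior;
  visits must record all biomarkers (the model is defined only at observed
  subject-time-biomarker triples, and no observation-level imputation is
  attempted).

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` exercise the full
pipeline at reduced sizes chosen to keep a complete run on one CPU within
minutes while preserving the phenomena of interest: the sample-size sweep
uses the regular design at $p = 30$, $k = 2$, $q = 8$ with 30 StEM
iterations (S-step chains of 150 scans, trailing window $m = 10$) and 12–20
replicates per sample size $n \in \{10, 50, 100\}$; Monte-Carlo checks of
the Gibbs conditionals use 20k–50k draws. Full-size analyses (e.g.
$p = 100$, $k = 4$, 200 StEM iterations, $10^5$-iteration Gibbs chains with
thinning 200) use the same code paths with larger configuration values.

## Known limitations

* The shared-base-process construction uses a single shared process: with
  $k > 2$ factors the reachable cross-correlation *patterns* are
  constrained (all pairwise correlations are products $v_{a0} v_{b0}$ times
  positive constants), although each pairwise magnitude remains flexible.
* The number of factors $k$ is fixed in advance; compare several $k$ in
  practice. If $k$ exceeds the number of factors the data can identify
  (e.g. a factor that regulates no biomarker), the estimated
  cross-correlation can drift toward a $\pm 1$ ridge on which two nearly
  identical factors carry large cancelling loadings — a recognizable
  signature of an over-specified $k$.
* The StEM/Gibbs machinery assumes Gaussian observation noise and linear
  biomarker-factor relationships.
* Posterior alignment handles label switching *post hoc*; in pathological
  multimodal posteriors a chain could still mix across modes faster than
  alignment can track.
* Computational complexity is $O(n k^2 q^2)$ per M-step objective
  evaluation and cubic in $k q$ for the per-pattern factorizations, so very
  irregular designs (large $q$) with many factors become expensive;
  coarsening to a reference grid (`map_to_reference_grid()`) is the
  provided mitigation.
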