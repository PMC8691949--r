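---
title: "Models and methods behind breathelearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breathelearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathelearn)
```

# Scope

`breathelearn` implements the computational analysis pipeline of a binary
interoceptive (breathing) learning experiment: associative-learning model
fitting and selection on an 80-trial cue-outcome task with probabilistic
inspiratory-resistance outcomes, model-based event-table construction for
neuroimaging software, type-2 signal-detection metacognition metrics for a
near-threshold filter detection task, and multimodal group statistics
including a permutation-tested PCA. Because the participant-level data of
such studies are typically access-restricted, the package ships a
first-class synthetic-data module; every downstream stage is exercised and
tested against cohorts the package generates itself.

Out of scope by design: all MRI acquisition/preprocessing, physiological
noise modelling, HRF convolution and voxelwise GLM inference (event tables
are the interface to external neuroimaging software), and hierarchical
MCMC estimation of metacognition (see below).

# The task and its synthetic schedule

Two visual cues carry mirrored probabilities (0.8 / 0.2) of a subsequent
inspiratory resistance. The pairing swaps at block boundaries: the default
block structure is [30, 10, 10, 10, 20] trials, giving 4 reversals after an
initial stable period of 30 trials. Block lengths divisible by 10 make the
80/20 proportions exactly realizable per cue within every block, and
resistance is delivered on exactly half of all 80 trials. Only the
within-block trial order and the inter-trial intervals depend on the seed;
all block-level counts are fixed by design. Published task descriptions fix
the reversal count and the stable period but not the later reversal
positions; the default positions here are a package choice made so that the
design constants are exact.

Timing defaults: cue 2.5 s, stimulus window 5 s, inter-trial interval drawn
uniformly from [7, 9] s. The duration of the post-stimulus rating period is
not reported in task descriptions; the default of 4 s is a documented
reconstruction and configurable.

One consequence of the mirrored-cue ("contingency space") outcome coding is
worth noting: although resistance occurs on exactly half of the trials, the
coded input `u` is *not* balanced. With the coding `u = 1` for
no-resistance-after-cue-1 / resistance-after-cue-2, `u` equals 1 with
probability `1 - p` in blocks where cue 1 is the high-resistance cue (60 of
80 trials in the default design) and `p` elsewhere, so `mean(u) = 0.35`.
The package's tests assert this counted value.

# Perceptual models

All three models operate on the contingency-space input `u(k)` and output
the trial-wise prediction `v(k)` (the probability that `u(k) = 1` predicted
*before* trial `k`) and the prediction error `delta(k) = u(k) - v(k)`.

* **Rescorla-Wagner (RW)** — `v(k+1) = v(k) + alpha * delta(k)` with a
  fixed learning rate `alpha` in [0, 1]. The initial belief `v0 = 0.5`
  (maximal uncertainty) is a package choice: participants are told that the
  cues are mirrored but not which cue is which, so the prior belief should
  carry no information. It is configurable.
* **Two-level hierarchical Gaussian filter (HGF2)** — a Gaussian random
  walk on the level-2 tendency whose sigmoid is the outcome probability;
  the free parameter is the evolution rate `omega2`.
* **Three-level HGF (HGF3)** — adds a level-3 log-volatility state coupled
  into the level-2 step size via `kappa2` (the free parameter); `omega2`
  and `omega3` are fixed.

The HGF update equations follow the variational scheme of the originating
toolbox (version 5.3 semantics for binary outcomes). The study's exact
fixed-parameter values live in supplementary material that is not
reproduced here; the package defaults (`mu2_0 = 0`, `sigma2_0 = 1`,
`mu3_0 = 1`, `sigma3_0 = 1`, `omega2 = -3`, `omega3 = -6`) are
reconstructions following common toolbox conventions, clearly overridable
through `hgf_fixed_params()`. Updates that drive a higher-level precision
non-positive raise a "trajectory invalid" error, which the fitting module
treats as a rejected parameter setting.

# Response model

Choices are linked to beliefs through the unit-square sigmoid

`p(y = 1 | v, zeta) = v^zeta / (v^zeta + (1 - v)^zeta)`,

computed internally as `logistic(zeta * logit(v))`, which is numerically
stable for large `zeta`. `zeta = 1` is probability matching, `zeta -> Inf`
argmax, `zeta = 0` guessing. Beliefs are clamped to `[1e-8, 1 - 1e-8]`
inside the likelihood so it stays finite; this guard only matters for
degenerate trajectories.

# Fitting, evidence, priors

MAP estimation runs BFGS in transformed space — `logit(alpha)`,
`log(zeta)`, identity for `omega2`/`kappa2` — with Gaussian priors and
seeded multi-start (default 10 restarts). One restart is seeded from a
coarse grid scan of the objective: the likelihood has a large flat plateau
at `zeta -> 0` (where all response probabilities are 0.5) on which
gradient-based optimisers strand, and the grid seed guards against missing
the narrow interior optimum. This defect mode is real: without the grid
seed, likelihood-ratio statistics on noise-only responders collapse to
zero.

The log model evidence is a Laplace approximation at the MAP estimate,
`lme = log-joint + (d/2) log(2 pi) - 0.5 log det(H)` with a
finite-difference Hessian; non-positive-definite Hessians are
ridge-regularised with a warning.

Default priors (used when no holdout cohort is supplied) are standard
Normals in transformed space centred on `alpha = 0.5`, the HGF fixed-value
defaults, and `zeta = 2`. `derive_priors()` implements the empirical
alternative: transformed-space means and variances of maximum-likelihood
estimates across a holdout cohort, with a variance floor for degenerate
holdouts.

## The chance-null exclusion test

Subjects whose fitted model does not beat the chance null
(`N log 0.5`) in a likelihood-ratio test at `df = 2` are flagged for
exclusion. A calibration caveat is documented rather than hidden: the
chance null lies on the *boundary* of the parameter space (`zeta = 0`, and
a non-identifiable ridge at `alpha = 0`), so the LR statistic follows a
chi-bar-square mixture that is stochastically smaller than chi-square(2).
The test is therefore conservative — on pure coin-flip responders it
excludes ~97-99% rather than the nominal 95%. The package reports the test
exactly as specified (`df = 2`, `p > 0.05` excludes) and its test suite
records the calibration honestly. The calibration check uses
maximum-likelihood fits; MAP shrinkage would make it more conservative
still.

# Model selection

`rfx_bms()` implements random-effects Bayesian model selection: a
variational Dirichlet posterior over model frequencies (uniform prior
`alpha0 = 1`), exceedance probabilities by seeded Monte-Carlo Dirichlet
sampling, the Bayesian omnibus risk from the free-energy comparison of the
frequency model against the equal-frequency null, and the protected
exceedance probability `PXP = (1 - BOR) * EP + BOR / K`. A winner is
declared only above the pre-specified `PXP > 0.90` criterion, mirroring the
analysis-plan convention.

`run_recovery_study()` reproduces the face-validity simulation: 60
synthetic subjects per generating model, perceptual parameters drawn from
the prior densities, decision noise `zeta_sim` in {1, 5, 10}, all models
refitted, Pearson correlations between simulated and recovered parameters,
LME confusion matrices with balanced accuracy, and the binomial 90%-CI
identification criterion (two-sided CI of `Binomial(n, 1/K)`, a package
reading of the stated criterion), averaged over 10 seeded iterations
(scaled to 3 in continuous-integration runs; stated in the test). One
caveat: with `zeta_sim = 0` responses carry no information and LME
differences reduce to deterministic complexity offsets, so identification
is systematic, not uniform.

# Model-based regressors

Fitted trajectories are mapped back to stimulus space (`v_stim = v` under
cue 1, `1 - v` under cue 2; prediction errors mirror with a sign flip), and
split by valence into certainty and error magnitudes: `v_pos = v_stim -
0.5` where `v_stim > 0.5`, `v_neg = 0.5 - v_stim` where `v_stim < 0.5`,
`delta_pos = delta_stim` where positive, `delta_neg = -delta_stim` where
negative. The defining inequalities are strict and leave the boundary
`v_stim = 0.5` unassigned; the package assigns zero magnitude to both
streams there, which preserves the exact reconstruction identities
`v_stim = 0.5 + v_pos - v_neg` and `delta_stim = delta_pos - delta_neg`
asserted in the tests.

`build_event_table()` emits the eight regressors (cue; positive/negative
prediction, 0.5 s, modulated; no-resistance/resistance stimulus;
positive/negative prediction error, 0.5 s, modulated; rating period) as a
BIDS-style events table. Prediction-error onsets use the schedule's
stimulus-period onsets — detecting true resistance onset from pressure
traces is out of scope. Zero-magnitude rows are retained rather than
dropped so row counts are schedule-determined. HRF convolution and GLM
estimation are deliberately not implemented.

Validation against unseen cohorts follows the study's logic: the
representative subject (learning rate closest to the cohort mean, ties to
the lowest index) provides the prediction trajectory, and a pooled logistic
regression of stacked unseen decisions on that trajectory tests whether it
explains behaviour it was not fitted to. Perfect separation triggers a
flagged ridge-penalised fallback.

# Filter detection task metacognition

The simulated observer is an equal-variance SDT agent with
`d'(filters) = slope * filters`, evidence `x ~ Normal(±d'/2, 1)`, and
"yes" iff `x > criterion`. Confidence maps `|x - criterion|` through the
folded standard-normal CDF onto deciles 1-10; metacognitive noise is
Gaussian jitter added before binning, which smoothly lowers the measured
Mratio below 1. The staircase reconstruction (the original algorithm lives
in a separate methods paper): a search phase starts at 1 filter and adjusts
by ±1 after 10-trial mini-blocks until accuracy enters the 60-85% band,
then a 60-trial constant phase with a ±1 adjustment whenever trailing
10-trial accuracy leaves the band. Observer-bank defaults
(`slope ~ lognormal(log 0.3, 0.25)`, `criterion ~ Normal(0, 0.15)`,
`conf_noise = 0.3`) were chosen once so that thresholds land in the 2-6
filter range around the reported group medians (3-4 filters) and
constant-phase accuracy sits inside the target band; they are not tuned to
any test outcome.

Measures per subject: perceptual threshold (modal constant-phase filter
count), decision bias `c` (negative = over-reporting resistance),
metacognitive bias (mean confidence over all constant-phase trials — the
alternative of accuracy-filtered trials is unspecified upstream, and "all"
is the package default), and metacognitive performance
`Mratio = meta-d'/d'`. meta-d' is fitted by **per-subject maximum
likelihood** under the standard response-conditional type-2 SDT model
(type-1 criterion held at the scaled relative criterion, confidence
collapsed to 4 bins at fixed edges {1-3, 4-5, 6-7, 8-10}, every cell padded
by `1/(2*n_bins)`). This deliberately replaces the hierarchical Bayesian
group fit used in the original analysis: it removes an MCMC dependency
while preserving the measured quantity. Consequences: per-subject Mratio
estimates are noisier and are not shrunk toward a group mean, so group
comparisons on these values are somewhat more conservative than the
hierarchical version.

# Multimodal statistics

Group comparisons are normality-gated: Anderson-Darling (composite null,
case-4 p approximation) in each group; t test with mean ± SE summaries if
neither group rejects, otherwise Wilcoxon rank-sum with median ± IQR.
Bonferroni families follow the analysis structure (e.g. 0.05/13 ≈ 0.004 for
a 13-questionnaire family, 0.05/4 = 0.0125 for the four detection-task
measures).

The 16-measure correlation matrix reports Pearson (optionally Spearman)
coefficients with two tiers: uncorrected p < 0.05 and Benjamini-Hochberg
FDR over the upper triangle. BH is the package default; the positive-FDR
estimator used by some toolboxes can differ slightly in which borderline
pairs survive.

`pca_significance()` z-scores each column, decomposes by SVD, and builds a
permutation null by independently shuffling every column across subjects
(ignoring group labels, per the stated procedure) and recording variance
explained per component rank. Component `k` is significant when its
observed variance explained exceeds the 95th percentile of its *matched
rank* null — the most common reading of rank-wise permutation tests.
Weights are sign-fixed (dominant loading positive) for reproducible
reporting; scores satisfy `t_k(i) = x_i . w_k` exactly. Significant
component scores are compared between groups with the same normality-gated
tests and BH-FDR across the significant components.

# What the synthetic world does and does not establish

The multimodal generator plants a dominant negative-affect factor (strong
loadings on the affective questionnaires, negative on positively-minded
interoceptive awareness, moderate on catastrophizing and body perception,
small on the metacognition measures) plus a weak second factor tying the
four brain-activity measures together, and group mean shifts that follow
the reported direction and approximate magnitude of the low- versus
moderate-anxiety contrasts (large on affective scores, none on vigilance or
brain measures). Green tests on this world establish that the pipeline
detects structure it should detect and stays calibrated when there is none.
They do not establish anything about real participants: empirical headline
numbers (group PXP ratios, the 58/60 null-model survivors, the validation
slope 3.1 ± 0.3, the two PCs with p < 1e-11) depend on access-restricted
data and are treated as reference values only, never as test expectations.

# Numerical choices

* Probability clamping `1e-8` in the response likelihood.
* Optimiser: BFGS, `reltol 1e-10`, 500 iterations, 10 restarts (3 inside
  the large simulation studies, stated where used), plus the grid-seeded
  restart.
* Laplace Hessian by `optimHess` finite differences; ridge regularisation
  on non-PD Hessians.
* Exceedance probabilities: 1e5 Dirichlet draws by default (4e6 in the
  quadrature-comparison test where 1e-3 agreement is asserted).
* Ties in representative-subject selection resolve to the lowest index,
  with a 1e-12 tolerance so exact ties are not broken by float noise.
* meta-d' optimisation parameterises type-2 criteria as cumulative
  exponentials, guaranteeing ordering.

# Known limitations

* The pseudorandom trial sequence of the original study is not public; the
  generator produces its own seeded sequences, so trajectory-level numbers
  are not comparable to the original single-subject figures.
* The LR exclusion test is conservative (boundary null; see above).
* HGF fixed parameters are reconstructions, not the study's supplementary
  values.
* The staircase is a reconstruction of a procedure documented in a
  separate methods paper; only its contract (accuracy band, constant
  phase) is reproduced.
* Per-subject ML meta-d' requires enough rating variability; degenerate
  sessions are flagged rather than estimated.
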