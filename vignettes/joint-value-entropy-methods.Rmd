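---
title: "Methods: joint coding of subjective value and decision entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint coding of subjective value and decision entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

During risky choice, two quantities travel together: the *subjective value*
(SV) of the option under consideration and the decider's *confidence* in the
choice they are about to make. `svide` implements a desk-scale pipeline for
asking whether voxels that encode SV also encode confidence — operationalised
as *inverse decision entropy* (iDE) — and whether the two signals share sign
and spatial organisation (aligned gradients) rather than living in disjoint
regions.

## The behavioural model

For a mixed-gambles task (accept/reject a 50/50 gamble with gain magnitude
$G$ and loss magnitude $L$), each participant's choices are modelled with a
logistic regression:

$$p_{\mathrm{accept}} = \mathrm{logit}^{-1}\!\left(\beta_{\mathrm{gains}} G +
\beta_{\mathrm{losses}} L + \beta_0\right)$$

Subjective value is the linear predictor without the intercept,
$\mathrm{SV} = \beta_{\mathrm{gains}} G + \beta_{\mathrm{losses}} L$, and
decision entropy is the binary Shannon entropy of the acceptance probability
(in bits):

$$\mathrm{DE} = -\left[p \log_2 p + (1-p)\log_2(1-p)\right],
\qquad \mathrm{iDE} = -\mathrm{DE}.$$

iDE lives in $[-1, 0]$: near 0 for confident decisions (either direction),
$-1$ when the model is indifferent. Loss aversion is the ratio
$-\beta_{\mathrm{losses}}/\beta_{\mathrm{gains}}$, typically near 2.

Two exact consequences anchor the validation suite: the inverse logit is
strictly monotone, so Spearman's correlation between tie-free SV and
$p_{\mathrm{accept}}$ is exactly 1; and both iDE and the subjective
probability of being correct, $\max(p, 1-p)$, are strictly increasing in
$|p - 0.5|$, so their rank correlation is also exactly 1. These are the two
quantities the acceptance script reports.

### Fitting choices and degenerate data

`choice_model()` maximises the likelihood by iteratively reweighted least
squares with a small always-on ridge penalty ($\lambda = 10^{-6}$), so the
normal equations stay invertible even when the data are separable. Separation
is detected by runaway coefficients ($|\hat\beta| > 10$), saturated fitted
probabilities, or a one-sided response vector; detection escalates the
penalty to $\lambda = 10^{-2}$ and flags the fit (`separable = TRUE`) rather
than returning infinities. The base-`glm` fit is used in the test suite as an
independent oracle on well-behaved data; it is never the implementation.

Missing (`NoResp`) trials are dropped both from fitting and from the event
regressors — the conservative default. Probability-correct uses the fitted
model's $p_{\mathrm{accept}}$, not observed accuracy, mirroring in-dataset
recomputation. Exclusion rules flag participants whose gain or loss
coefficient lies beyond 2.3 group SDs of the group mean (SD computed with the
candidate included, `ddof = 1` — the simplest reproducible convention) or
whose mean framewise displacement exceeds the group mean by 2.3 SDs. The
framewise-displacement summary is the per-participant *mean*; max-based
summaries are equally defensible but less stable at desk scale. With zero
group SD no coefficient exclusions are made. The weak/strong comparison uses
an unequal-variance (Welch) two-sample t on per-participant mean iDE for weak
vs strong responses, reported as strong minus weak.

## The synthetic dataset

The generator inverts the analysis model so every downstream stage has a
known answer. Conditions it emulates:

* **Task.** Gains and losses crossed orthogonally; `equal_range` uses
  identical gain and loss levels, `equal_indifference` halves the loss range.
  Default levels are `seq(5, 40, 5)` for gains (the exact experimental level
  sets are configuration, not constants), 64 trials per run — the full
  8&times;8 crossing — and four runs. Trials last 4 s with inter-trial
  intervals uniform on 2–6 s (any jitter suffices for identifiability),
  TR = 1 s.
* **Behaviour.** Choices are Bernoulli draws at the model's
  $p_{\mathrm{accept}}$; cohort coefficients are lognormal around
  $\beta_{\mathrm{gains}} = 0.1$ with loss aversion around 2. The 4-level
  response is generated by thresholding probability-correct at
  $\theta = 0.75$ (configurable; only the weak/strong *ordering* is a model
  prediction, so any $\theta > 0.5$ preserves it).
* **BOLD.** Each voxel's time series is the HRF-convolved trial boxcar
  weighted by an intercept map, plus SV- and iDE-modulated boxcars (mean
  centred, exactly as in the analysis design) weighted by smooth ground-truth
  maps, plus slow cosine drift, optional motion-coupled signal (off by
  default), and stationary AR(1) noise ($\rho = 0.3$). The default noise SD
  is *matched to the SD of the noiseless task signal* across voxels and time
  — the reference signal-to-noise condition for the recovery checks.
  `sigma = 0` with filters bypassed gives exact first-level recovery of the
  weight maps (tested to $10^{-6}$ relative; in practice it holds to machine
  precision because generator and design builder share one convolution
  routine).
* **Ground-truth maps.** `aligned` mode builds two smooth fields sharing a
  linear gradient along one axis (jointly positive at one end, jointly
  negative at the other, sign agreement &ge; 95%); `independent` draws two
  unrelated smooth Gaussian fields (sigma 2 voxels); `opposed` flips one
  sign. The gradient's zero-crossing (`neg_fraction`) can track each
  subject's loss aversion, which is how the loss-aversion voxel-ratio
  analysis gets a recoverable signal.

What the generator does **not** emulate: physiological noise, spikes,
susceptibility artefacts, anatomical structure, or realistic spatial
covariance of real BOLD. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to everything real
data does.

## First-level GLM

Per run: 5 mm FWHM Gaussian smoothing (kernel rows renormalised at the
boundary so constants are preserved); a design with a trial regressor and SV
and iDE parametric modulators — amplitudes mean-centred across the run's
trials *before* convolution, no orthogonalisation between regressors —
convolved with the canonical double-gamma HRF (delays 6/16 s, dispersions 1,
undershoot ratio 1/6, unit peak) at 0.1 s microtime, then sampled at the TR;
temporal derivatives of each convolved task column by central differences;
seven motion confounds (FD, three rotations, three translations) unconvolved;
and a constant.

Numerical choices worth stating:

* **High-pass (100 s cutoff).** A projection onto the orthogonal complement
  of a drift basis: discrete cosines with periods above the cutoff,
  augmented with constant and exact linear terms so pure trends are removed
  completely (a finite cosine set alone only attenuates a ramp). The same
  projection is applied to data and regressors; it is idempotent.
* **Serial correlation.** Per-voxel AR(1) Cochrane–Orcutt prewhitening: OLS
  residuals give $\hat\rho$ (clamped to $\pm0.95$, rounded to 0.01 so voxels
  sharing a $\hat\rho$ reuse one whitened solve), then one refit on the
  lag-differenced data and design. This is a documented stand-in for
  tool-specific locally regularised autocorrelation estimators: same
  contract (valid variances under serial correlation), far simpler. Type-I
  calibration under AR(1) noise is tested.
* **Run pooling.** Fixed effects: inverse-variance weighted means, pooled
  variance $1/\sum v_i^{-1}$, $Z = \beta/\sqrt{v}$.

Because modulators are mean-centred, adding any constant to all SV values
leaves the SV beta untouched (tested to $10^{-8}$); and because the model is
fit jointly, correlated (non-orthogonalised) modulators still identify the
generating weights exactly in the noiseless case.

## Group level and inference

* **One-sample maps.** Method-of-moments random effects across subjects:
  voxelwise mean and sample variance, one round of Huber reweighting
  (c = 1.345 on standardised residuals) when `deweight = TRUE`, t with
  n − 1 df mapped to a standard-normal Z (log-scale tail conversion, stable
  to |Z| ≈ 38). This is a deliberate, logged stand-in for two-stage Bayesian
  mixed-effects estimation; the contract preserved is between-subject
  variance plus outlier robustness.
* **Cluster inference.** Threshold at z = 2.3, 26-connected components,
  family-wise corrected cluster p from a sign-flip permutation null of the
  maximum cluster extent (the estimator $(1+k)/(B+1)$). Permutation replaces
  Gaussian-random-field theory: GRF smoothness estimation is heavy and
  tool-specific, while sign-flip permutation gives exact FWE control at desk
  scale. Negative-tail inference negates the maps. Under smooth null maps
  the realised FWE is 0.05 within Monte-Carlo error; under unsmoothed white
  noise cluster extents are tiny and heavily tied, and the test becomes
  conservative — a discreteness effect, not an error.
* **Conjunction.** Minimum statistic: $Z_{\mathrm{conj}} = \min(Z_A, Z_B)$,
  clustered like a main effect, with permutations flipping both parents'
  subjects jointly. A voxel can only survive if both effects individually
  exceed the threshold.
* **SV vs iDE contrast.** Paired sign-flip permutation test on subject-level
  Z differences (both directions), 5000 permutations at alpha = 0.01.
  One-tailed permutation p converted to Z via $\Phi^{-1}(1-p)$ — so the
  attainable Z saturates at $\Phi^{-1}(1 - 1/(B+1))$, which for B = 5000 is
  3.54; this is why peak Z values from such contrasts pile up at one value.
  Each direction is conjoined with its main effect and masked by the sign of
  $|Z_{\mathrm{iDE}}| - |Z_{\mathrm{SV}}|$; voxelwise FWE correction uses
  the max-statistic distribution from the same permutations.

## Joint-coding statistics

Significant voxels per variable and sign are taken from the whole-brain
corrected cluster maps intersected with the task-active mask (voxels with
$|Z| \ge 2.3$ for the unmodulated trial regressor); an uncorrected-threshold
variant is available via the exported building blocks, since reasonable
analysts differ here. On voxels significant for *both* variables:

* **Sign contingency:** 2&times;2 table of sign pairs, expected cells from
  the marginals, chi-squared with df = 1 and no continuity correction;
  percentages reported to one decimal.
* **ROI overlap:** percentage of jointly significant ROI voxels with
  matching signs (undefined, not crashing, for empty ROIs). Probabilistic
  masks are binarised at 50% after nearest-neighbour resampling.
* **Map correlation:** Pearson r between the two group maps across masked
  voxels — two maps only, one per variable.
* **Gradient map:** each map z-scored across the mask, then summed; near
  zero marks cancellation, large magnitudes joint coding.
* **Loss-aversion voxel ratio:** per subject, negative/positive
  supra-threshold SV voxel counts, rank-correlated with behavioural
  $-\beta_{\mathrm{losses}}/\beta_{\mathrm{gains}}$.

A caution that the package makes explicit: the chi-squared test assumes
independent voxels. Its nominal calibration is verified on independent sign
draws (rejection rate 0.05 ± 0.02 over 1000 draws). On spatially smooth
maps — which is what the pipeline produces, by construction — neighbouring
voxels share sign, the effective sample is far smaller than the voxel count,
and the statistic is overdispersed: even with truly independent SV and iDE
fields the pipeline-level chi-squared is usually "significant". The
contingency result should therefore be read jointly with the map
correlation (which is robust to this) rather than as a calibrated test.

## Problem sizes and reproducibility

Default geometry is 20&times;20&times;20 voxels at 3 mm, 24 subjects,
4 runs &times; 64 trials at TR = 1 s — a full pipeline run completes in
under 15 minutes on one CPU. The test suite uses this default for the
aligned-mode recovery run; the independent-mode replicate runs use a
16&sup3;/12-subject geometry, the null-calibration studies 12&sup3; with 99
permutations per repetition, and cluster permutations default to 500 in the
desk configuration (the paired contrast keeps the full 5000, which sets its
Z saturation). Every stage seed derives deterministically from the master
seed; identical configurations reproduce identical numbers, and
re-running the joint-coding stage on cached group maps reproduces the full
run exactly.

## Known limitations

* The mixed-effects stand-in is not a Bayesian two-stage estimator; with
  very small cohorts its Z maps are mildly conservative.
* Cluster p-values are permutation-based; with few subjects the number of
  distinct sign flips bounds attainable significance.
* The behavioural model omits run effects (the model is fit across runs),
  reaction times, and alternative value definitions.
* At 256 trials the intercept of the choice model is weakly identified on
  currency-scaled gamble grids (it extrapolates to the gamble-grid origin);
  the gain and loss weights themselves recover an order of magnitude more
  tightly than the intercept.
* Whether derivative regressors should be modulator-specific is ambiguous
  in common practice; the package includes one derivative per convolved
  task column.
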