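# svide — joint coding of subjective value and decision entropy

`svide` is an R package for asking a question from decision neuroscience:
do brain voxels that encode the **subjective value** (SV) of a risky option
also encode the decider's **confidence**, and do the two signals share sign
and spatial organisation? Confidence is operationalised as **inverse decision
entropy** (iDE) — the negative binary Shannon entropy of the model's
acceptance probability. The package is aimed at methodologists who want a
fully self-validating, desk-scale implementation of the model-based fMRI
workflow behind that question: every stage can be run against synthetic data
with known ground truth.

## The model

For a mixed-gambles task (accept or reject a 50/50 gamble with gain `G` and
loss `L`), each participant's choices follow a logistic model:

    p_accept = logit⁻¹(β_gains·G + β_losses·L + intercept)
    SV       = β_gains·G + β_losses·L
    DE       = −[p·log₂ p + (1−p)·log₂(1−p)],   iDE = −DE

Loss aversion is `−β_losses/β_gains` (≈ 2 in typical participants). SV and
iDE then enter a voxelwise GLM as mean-centred parametric modulators
(double-gamma HRF, temporal derivatives, 7 motion confounds, 100 s cosine
high-pass, AR(1) prewhitening, 5 mm smoothing), runs are pooled with fixed
effects, subjects with method-of-moments random effects plus Huber
deweighting, and inference uses sign-flip permutation cluster correction
(z = 2.3, α = 0.05), minimum-statistic conjunctions, and a 5000-permutation
paired contrast of SV vs iDE. Joint coding is summarised by a 2×2 sign
contingency with χ², ROI sign-overlap percentages, voxelwise map
correlations, z-scored gradient summation maps, and the loss-aversion voxel
ratio.

A synthetic-data module generates the whole stack — gamble schedules,
choices from known coefficients, and 4D BOLD with spatially smooth
ground-truth SV/iDE weight maps — so recovery is checkable end to end.

## Worked example

Fit the choice model to one simulated participant (64 gambles from the full
gain × loss crossing) and inspect the derived quantities:

```r
library(svide)
g <- expand.grid(gain = seq(5, 40, 5), loss = seq(5, 40, 5))
truth <- true_choice_model(0.12, -0.24, 0.1)
g$accept <- simulate(truth, seed = 2, newdata = g)$accept
fit <- choice_model(accept ~ gain + loss, g)
summary(fit)
#>              Estimate Std. Error z value  Pr(>|z|)
#> (Intercept) -0.888147   1.053558 -0.8430 0.3992296
#> gain         0.103129   0.039027  2.6425 0.0082294
#> loss        -0.155752   0.046710 -3.3345 0.0008546
#> Loss aversion: 1.51
```

The fitted gain weight (0.103) and loss weight (−0.156) recover the
generating 0.12/−0.24 pattern at 64 trials; `trial_values(fit)` returns
per-trial `sv`, `p_accept`, `de`, `ide` and `p_correct`.

Run the full synthetic pipeline at the default study scale (24 subjects,
20³ voxels, aligned ground-truth gradients; ~8 minutes on one CPU):

```r
rep <- run_pipeline(default_config(seed = 11))
rep
#> Pipeline run: 22 of 24 subjects kept; mode = aligned
#> Sign contingency: chi2 = 7054.24 (p = 0), diagonal 97.8%
#> Whole-mask SV~iDE beta correlation: r = 0.980
```

Here 97.8% of voxels significant for both variables share sign (the
diagonal of the 2×2 table) and the group-level SV and iDE beta maps
correlate at r = 0.98 — the aligned ground truth is recovered. With
`mode = "independent"` the correlation collapses toward zero. A smaller
demonstration (`n_subjects = 5`, 8³ grid) runs in ~10 s; at that scale
alignment is so clean that one sign class is empty and the χ² is reported
as undefined rather than a number.

A thin command-line wrapper lives at `inst/cli/svide`
(`svide run-all --seed 7 --out out/`).

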