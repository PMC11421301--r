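---
title: "Dual change score models for frailty and epigenetic aging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual change score models for frailty and epigenetic aging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsm)
```

## The model

`dcsm` fits dual change score models (DCSMs) to longitudinal aging
traits observed at irregular visit ages. Two traits are of particular
interest in this package's presets: a deficit-accumulation frailty index
(FI, 0–100%) and a DNA-methylation epigenetic clock (either an
age-trained clock in years or a pace-of-aging clock, which is modeled on
a 10× scale so that its parameters are on a comparable numeric footing).

Chronological age is the timescale. Ages are split into half-open 2-year
bins, by default $[50, 52), \dots, [88, 90)$; data at or past age 90 are
dropped as unassignable. Within each trait, the latent (true-score)
process evolves across bins as

$$\Delta y_t \;=\; \alpha \cdot S \;+\; \beta \, y_{t-1}
  \;+\; \gamma \, x_{t-1},$$

where $S$ is a person-specific slope factor with $\alpha$ fixed to 1
(the constant change component), $\beta$ is the proportional change
effect producing accelerating or decelerating trajectories, and, in
bivariate models, $\gamma$ couples the *other* trait's previous level
into this trait's change — the lead–lag parameter that operationalizes
temporal precedence. The observed score is the latent score plus an
occasion residual; placing the dynamics on the latent scale keeps the
residual variance separate from the change system, which is the standard
latent change score reduction.

Each person carries intercept and slope factors per trait with means
$\mu_I, \mu_S$, sex effects added to the factor means (women vs men; sex
never enters variances), and a $4 \times 4$ covariance matrix of
(FI intercept, FI slope, clock intercept, clock slope). To account for
twin relatedness, a second, twin-pair-level set of factors with its own
covariance matrix is shared by co-twins. This separates family-level
from individual-level variation without an explicit MZ/DZ genetic model;
zygosity is carried as metadata only. Residuals have per-trait variances
constant over age, one within-person within-bin covariance between the
two traits, and no correlation across bins or across twins.

Because the dynamics are linear in the growth factors, the latent score
at bin $t$ is an explicit linear combination of the factors, obtained by
a forward recursion on loading vectors (bin 0 loads only on the
intercepts). The model therefore implies, per twin pair, a
multivariate-normal distribution over the stacked layout (2 twins × 2
traits × 20 bins), and estimation maximizes the casewise
(full-information) likelihood: each pair contributes the normal
log-density of exactly its observed entries. Missing co-twins are
all-missing twins — no special-case likelihood. A pair with no
observations contributes zero.

## Estimation choices

The optimizer works on an unconstrained vector: covariance blocks enter
through lower-triangular square roots ($\Sigma = CC'$), so every iterate
is positive semi-definite; residual variances through logs; the residual
cross-trait covariance through a tanh-bounded correlation. Structural
zeros (couplings or proportional effects a specification switches off,
or pair-level slope factors dropped under the per-trait
`pairLevel = "intercept"` reduction used for pace-of-aging models) carry
no degree of freedom.

Default starts are data-driven: bin-0 trait means (falling back to a
pooled regression intercept when the first bin is sparse), the mean of
per-person least-squares slopes, $\beta = \gamma = 0$, diagonal factor
covariances sized from the marginal trait variances. Quasi-Newton (BFGS)
runs restart from the previous optimum until the relative objective
change is below 1e-8; convergence additionally requires the
finite-difference gradient to be small relative to the objective
magnitude (max $|g| < 10^{-4}(1 + |\ell|)$ — an absolute gradient
tolerance is not meaningful for log-likelihoods of magnitude $10^4$
computed with finite differences). Non-convergence is reported through a
flag, never silently. Standard errors come from the observed information
matrix at the optimum, mapped to the natural scale (variances,
covariances, means) by the delta method; when the information matrix is
singular the SEs are reported as `NA`.

The per-pair likelihood loop is compiled (RcppArmadillo): the implied
mean and covariance are built once per evaluation (covariance is
sex-invariant because sex enters means only), and each pair's observed
sub-matrix is factorized directly. At the cohort sizes used here this is
cheaper than caching moments per missingness pattern, because patterns
are nearly unique across pairs.

Model comparison uses likelihood ratio tests with the naive chi-square
reference. For contrasts involving variance components at the zero
boundary this reference is conservative; mixture references are out of
scope and the caveat is documented in `likelihoodRatioTest()`. Nested
fits are warm-started from the encompassing fit (and the encompassing
fit re-started from a better-scoring nested optimum if one appears), so
the nesting inequality $\ell_{full} \ge \ell_{nested}$ holds in
practice. The selection ladders mirror the published analysis strategy:
univariate models retain the proportional term iff dropping it
significantly worsens fit at $\alpha = 0.05$; bivariate models first
compare bidirectional coupling to no coupling, and only if no-coupling
is rejected are the two unidirectional models compared to the
bidirectional one. A tie between unidirectional branches is reported,
not silently broken.

## The synthetic cohort

The real cohort this design emulates (SATSA, the Swedish Adoption/Twin
Study of Aging) is deposit-restricted, so the package ships a generator
rather than data. Its defaults are the study conditions: 524 individuals
in same-sex twin pairs, 58.6% women, visit counts distributed as
157/123/113/89/41/1 over 1–6 waves (≈1,309 scheduled visits), 3–6 years
between waves. Values the source design does not state were fixed once:

* **Entry ages** uniform on [50, 84]; later waves run past 90 and are
  dropped at binning, like real out-of-range visits. This reproduces a
  plausible baseline-age distribution and loses about 5% of scheduled
  visits (computed from the design, not tuned), so a simulated cohort
  carries ≈1,240–1,310 visits.
* **Pair fraction** 0.5 — half the individuals have a participating
  co-twin. Aging twin cohorts typically contain many singletons
  (deceased or non-participating co-twins); the singleton share of the
  emulated study is not published.
* **Visit ages are non-informative.** Real attrition correlates with
  frailty; that informative-missingness mechanism is deliberately not
  simulated, so passing recovery tests demonstrate correctness of the
  estimator under the model's own missing-at-random assumption, not
  robustness to selective drop-out.

Generating parameter presets (`presetModel()`) use published-magnitude
values for the FI-plus-pace and FI-plus-PC-clock models. Covariance
tables printed to two decimals are not exactly positive semi-definite
when variance components sit near zero (e.g. a slope variance printed
0.00 next to a covariance of −0.61); the presets repair the active
blocks by eigenvalue clipping (`nearPsd()`), which perturbs second
moments by at most a few hundredths and leaves means and dynamics
untouched. Simulated FI values are not clipped to [0, 100] by default —
the Gaussian model has no bounds — and a `clipFI` stress flag exists for
sensitivity checks.

## Numerical and statistical conventions

* Half-open bins: boundary ages belong to the lower bin, matching the
  "50 to <52" convention; the intercept is defined at the start of the
  first bin (exact age 50), not its midpoint.
* Two visits in one bin: the chronologically earlier non-missing value
  is kept per trait, with a warning — deterministic and auditable.
* Deficit items may be binary or ordinal in [0, 1]; unavailable items
  shrink the FI denominator and an all-missing record is an error, not
  a zero.
* PSD guard: factor covariance eigenvalues down to −1e-10 are tolerated
  (they arise from finite arithmetic); harder violations raise errors
  rather than being repaired silently.
* Baseline correlations residualize both traits on exact (not binned)
  age with a linear term; "baseline" is each person's first observed
  visit.
* Trajectory curves average the sex-specific mean curves with a chosen
  proportion of women; vector-field arrows evaluate the fitted change
  equations exactly at each lattice point (pace lattice on the original
  scale, rescaled internally), and the 95% ellipse uses the sample
  moments of the baseline points at the chi-square(2) radius.

### Multiplicity in simulation-based checks

Two of the package's own acceptance-style checks compare many quantities
at once: parameter recovery (≈30 free parameters, each mean estimate
compared to its generating value in Monte-Carlo SEs) and moment
consistency (≈3,300 moment entries compared to their analytic values in
sampling SEs). A fixed per-quantity band of 2 (or 3) SEs would be
exceeded somewhere by a *correct* implementation with near certainty —
the expected number of 3-SE exceedances among 3,300 standard-normal
deviates is about nine. The tests therefore hold every quantity to a
Šidák-adjusted familywise bound at the 5% level (≈4.3 SEs for 30
parameters at 10 replicates, ≈4.3 SEs for 3,300 entries) and
additionally require the unadjusted 3-SE band for ≥99% of moment
entries. These bounds were fixed before the checks were first run.

The SE-calibration check (mean reported SE vs replicate SD) is applied
to mean-structure parameters only: variance components generated near
the zero boundary (pair-level slope variances of ≈0.1 with SEs of the
same size) have skewed, boundary-censored sampling distributions where
the observed-information SE is not expected to match the replicate SD.
With 10 replicates the SD itself is only estimated to ~25% relative
precision, so the band is set at 50%.

### Problem sizes

The shipped checks use the full 524-person design for recovery (10
replicates per model), a half-size design (262 persons) for the
selection-calibration runs — type-I error calibration does not depend on
n — and 100,000 complete pairs for the moment consistency check. The
selection power demonstration uses a strengthened coupling (γ = 2.5 with
the slope mean offset to keep trajectories in range), because at the
published effect size (γ = 1.19, ≈2.8 SEs) the published selection
ladder itself reproduces its outcome in only about half of replicates —
a property of the design's power, not of the implementation.

## A worked example

```{r example, eval = FALSE}
m <- presetModel("pace")
ds <- simulateDataset(m$spec, m$params, studyDesign(), seed = 1)
fit <- fitDcsm(m$spec, ds)
fit

sel <- bivariateSelection(ds, proportional = c(TRUE, FALSE),
                          pairLevel = c("full", "intercept"))
sel

vf <- vectorField(fit, ds)
plotVectorField(vf, arrowScale = 0.5)
plotTrajectories(trajectoryCurve(fit, sexMix = 0.586), ds)
```

## Known limitations

* Discrete 2-year dynamics only; no continuous-time formulation,
  unequal bin widths, or more than two coupled traits.
* The naive chi-square LRT reference for variance-component boundaries.
* No MZ/DZ genetic decomposition — a single pair-level covariance.
* Sex enters means only, and sex-stratified fits are not provided.
* Coupling evidence is a lead–lag association under the model's
  assumptions, not proof of causality; informative attrition is neither
  modeled nor simulated.
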