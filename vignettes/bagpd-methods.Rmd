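---
title: "Brain age gap and Parkinson's progression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age gap and Parkinson's progression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bagpd` implements an end-to-end analysis linking the *brain age gap* (BAG
— estimated brain age minus chronological age, a structural-MRI biomarker
of brain integrity) to Parkinson's disease (PD) progression: latent-time
alignment of longitudinal cohorts, brain-age estimation with bias
correction and reliability checks, covariate-adjusted progression
statistics, event-free survival, and prognostic-enrichment power
calculations for clinical trials. Because the clinical data this kind of
study uses (e.g. PPMI) is access-controlled, the package ships a
first-class synthetic cohort generator with known ground truth; every
downstream module is validated by parameter recovery against that truth.

# The latent-time joint mixed-effects model

Observed clinical scores are first min–max normalized to their theoretical
ranges and direction-harmonized (scores where higher is better, such as a
cognitive screen, are inverted) so that all progression slopes are
positive. The generative model for outcome $k$ of subject $i$ at visit $j$
is

$$y_{ijk} = x_i^\top \beta_k + \gamma_k (t_{ijk} + \delta_i)
  + \alpha_{0ik} + \alpha_{1ik} t_{ijk} + \varepsilon_{ijk},$$

with time $t$ measured since diagnosis, covariates $x_i$ (age at
diagnosis, sex), outcome-specific fixed slopes $\gamma_k$, a per-subject
*time shift* $\delta_i \sim N(0, \sigma_\delta^2)$ **shared across
outcomes**, mean-zero random intercepts/slopes, and normal noise. The
latent disease time $t + \delta_i$ aligns subjects on a common disease
timescale; 0 corresponds to the cohort's average stage at diagnosis.

## Sampler

The published analyses this package mirrors used an off-the-shelf
HMC backend; here the posterior is sampled by a purpose-built blocked
Gibbs sampler, which is exact for this model class: given the bilinear
$\gamma_k\delta_i$ term, every full conditional (regression coefficients,
shifts, random effects, variances) is conjugate normal or inverse-gamma.
Three *likelihood-invariant interweaving sweeps* are essential for mixing
and are sampled as ordinary Gibbs steps on reparametrized directions:

1. global: $(\delta + c,\ \beta_{0k} - \gamma_k c)$ — the overall location
   of the shifts is identified only by the mean-zero prior;
2. per subject: $(\delta_i + e_i,\ \alpha_{0ik} - \gamma_k e_i)$ — a
   subject's shift trades against its random intercepts;
3. per outcome: $(\gamma_k + e,\ \alpha_{1ik} - e,\ \alpha_{0ik} - e\delta_i)$
   — a fixed slope trades against the mean of its random slopes.

Without these sweeps the flat directions of the hierarchy mix as slow
random walks and split-$\hat R$ stays far above 1.05 at desk scale.

## Priors and settings

The literature states the mean-zero normality assumptions but no priors;
we use weakly informative conjugate defaults ($\beta, \gamma \sim
N(0, 10^2)$; inverse-gamma shape 2 on variances with scales 0.001
(residual), 0.0025 / 1e-4 (random intercept / slope), 1 ($\sigma^2_\delta$)).
With a 150-subject cohort the data dominate these priors by 2–3 orders of
magnitude. Random effects use diagonal covariance by default (full
multivariate normality of $(\alpha_0, \alpha_1)$ is not modeled), trading
a little fidelity for sampler stability. Convergence is judged by
split-$\hat R < 1.05$ on $\gamma$, $\delta$, and $\sigma_\delta$; a fit
above threshold is flagged, never silently returned. The full-scale
protocol (4 chains × 25 000 iterations, 12 500 warm-up) is accepted via
`ltjmm_spec()`; the desk-scale default is 4 × 4 000 / 2 000, which already
reaches $\hat R \approx 1.01$ and changes posterior means of $\delta$ by
an RMS < 0.05 y when iterations double.

Subjects with a single visit are retained (their $\delta$ posterior
reverts to the prior); latent-time validation uses Kendall $\tau_b$
against an ordinal stage, with a subject-level bootstrap for the
difference between $\tau(\text{stage}, \text{latent time})$ and
$\tau(\text{stage}, \text{time since diagnosis})$.

# The synthetic world

The generator draws exactly from the model above. Stated-world defaults:
172 HC / 451 PD; PD subtype mixture fast 14.6 %, slow 65.4 %, unknown
20.0 %; $\sigma_\delta = 1.0$ y; baseline within two years of diagnosis
(uniform); six-monthly visits with geometric dropout over at most 8 years.
Outcome slopes are 0.02–0.035 normalized units/year (≈ 2–4 raw points/year
on typical motor scales). Subtypes scale a subject's progression rate via
the mean of the random slope (fast ×2.0, slow ×0.78, unknown ×1.0 — chosen
so the mixture-weighted mean is ≈ 1 and $\gamma_k$ keeps its cohort-level
meaning). Values outside the theoretical score range are clamped and
flagged; the clamped fraction stays below 2 % under defaults.

Two defaults deserve justification:

* **Random-intercept sd 0.03** (normalized units, ≈ 4 raw UPDRS-III
  points). This is the residual baseline heterogeneity *beyond* disease
  stage and covariates; values much larger (e.g. 0.10 of the score range)
  would make covariate-adjusted scores implausibly noisy at baseline and
  would also make the time shift essentially unidentifiable for any
  method, contradicting the premise of latent-time alignment.
* **Scan noise sd 16 template units**. The literature pins retest
  reliability of BAG only through a concordance correlation of ≈ 0.86–0.89
  at short rescan intervals; the implied within-subject noise is not
  stated. Per the declared calibration rule, the default is set so the
  generator's population CCC lands in [0.8, 0.95]; this is a documented
  modeling choice, not a literature value.

Feature grids (default 16³ voxels, spherical mask, analytic
cortical-shell/subcortical-core partition instead of a real atlas) stand
in for normalized gray-matter maps. Per scan:

$$v = \mathrm{template}(v) - a(v)\,(\mathrm{age} - 40 + u_i + d_i(t))
      - 0.5\, b_{\text{subtype}}(v)\, d_i(t) + \eta,$$

where $u_i \sim N(0, 5^2)$ y is a stable brain-aging offset, and
$d_i(t) = \mathrm{accel}_{\text{subtype}} \cdot \max(0, t_{dx} + \delta_i)$
is accelerated aging along the *normal* atrophy pattern (fast ×2.0,
slow ×0.6), plus a subtype-specific spatial excess (fast: shell, slow:
core) that carries the morphometry contrast. Routing most of the disease
signal through the normal aging pattern guarantees that any competent
brain-age model reads it out as an increased BAG of about $d_i$ years —
the construction the enrichment analyses rely on — and yields a PD-mean
BAG of ≈ 1 y with fast-subtype means of ≈ 2–3 y, the magnitudes reported
for early PD. Spatial maps are a fixed function of grid geometry (internal
seed), so models trained on one simulated cohort apply to another; the
user seed drives only noise, schedules, and subject draws. What the
generator does **not** emulate: real neuroanatomy, scanner/site effects,
registration error, demographic confounding between age and disease. A
green test therefore establishes internal statistical correctness, not
radiological realism.

# Brain age estimation

Workflows combine Gaussian smoothing (separable truncated kernel,
$\sigma = \mathrm{FWHM}/2.3548$, edge-renormalized so constants are
preserved and interior mass is conserved), integer-factor linear
resampling, optional PCA (95 % variance), and a regressor: lasso
(`glmnet`, penalty by inner CV), ridge, or an RBF kernel ridge with
median-heuristic lengthscale and fixed nugget 0.1 — the GP posterior mean;
the literature pins neither kernels nor hyperparameters, so these are
package choices. The three named workflows are S4_R4+GPR, S4_R4+PCA+GPR
and S0_R4+LR.

Bias corrections are the two standard linear recalibrations, fitted on HC
only: *Cole* (regress predicted age on age; invert the fit) and *Beheshti*
(regress the gap on age; subtract the fit). Applying a correction to its
own training HC forces mean BAG = 0 and corr(BAG, age) = 0 exactly — the
OLS residual identities; these are the package's two deterministic
acceptance targets. Workflow × correction selection is by k-fold CV MAE
on HC (folds age-quantile-stratified by default — the literature does not
say; a flag disables it), ties broken toward fewer pipeline stages.
Reliability: Lin's CCC (population moments; the $n$ vs $n-1$ distinction
is negligible at these sizes) on rescans < 1.5 y apart, and the Pearson
correlation of the brain-age increase with elapsed time for intervals
≥ 1.5 y (half-open split; first and last scans when more than two exist).

# Progression statistics

Group BAG contrasts use `lm(BAG ~ group + age + sex)`, with latent disease
time added automatically exactly for the fast-vs-slow contrast. BAG
trajectories and per-outcome progression slopes use `lme4` random-slope
models; per-subject slopes are empirical-Bayes conditional modes, with a
documented fallback to per-subject OLS when the residual variance estimate
collapses (noise-free data), where OLS is exact. P-values for mixed-model
fixed slopes use the normal approximation (no Satterthwaite machinery in
the dependency set). Partial correlations are residual-on-residual Pearson
(age as covariate; latent time additionally for baseline targets), BH
corrected *within* each outcome family. Survival is Cox partial likelihood
(`survival`), Efron ties, with *delayed entry* at the baseline latent time
— our reading of "time modeled on the latent disease timescale"; PH
diagnostics are score tests on scaled Schoenfeld residuals (KM transform),
BH-adjusted. The cognitive-decline event is operationalized as the first
visit whose ordinal cognitive state exceeds the *baseline* state;
transient improvements do not reset the baseline.

# Trial power and prognostic enrichment

The cognitive composite z-scores each test against baseline mean/sd,
inverts where needed, and averages; its baseline mean is 0 by
construction. Per-arm sample size for detecting a fractional reduction
$f$ of the mean slope $\mu$ under a random-slope model with fixed visit
schedule $t_j$:

$$n/\text{arm} = \frac{2\,(z_{1-\alpha/2} + z_{\text{power}})^2
  \left(\sigma_s^2 + \sigma_e^2 / \sum_j (t_j - \bar t)^2\right)}
  {(f\mu)^2},$$

rounded up (for the default schedule 0, 0.5, …, 2 y,
$\sum (t_j-\bar t)^2 = 2.5$). The factor 2 is the two-arm comparison;
a Monte Carlo validator (full trial simulation, per-subject OLS slopes,
Welch test — exact for a shared balanced schedule) reproduces the target
power within ±0.05, which fixes the formula's normalization empirically.
$\alpha = 0.1$ is interpreted two-sided (a one-sided flag exists); the
treatment affects the mean slope only. Enrichment selects subjects with
baseline BAG *strictly above* the empirical percentile of the full PD
analysis set, re-estimates all three variance components on the subgroup
(a flag could reuse full-cohort residual variance; we re-estimate), and
reports sample sizes and reductions relative to the unstratified design.

# Numerical and degenerate-input conventions

* Exactly zero residual variance makes the mixed-model scale degenerate;
  noise-free checks use either the OLS fallback (slopes) or a tiny
  simulated noise (LTJMM).
* Rank-deficient GLM designs error; individual features with zero residual
  variance are flagged `NA`, not crashed.
* Empty retest/consistency sets report `NA` statistics rather than
  fabricating values.
* All randomness flows from one user seed through fixed per-stage child
  seeds (32-bit safe), so stages can be regenerated independently and
  identical inputs give byte-identical outputs.

# Known limitations

The morphometry t-maps share subject-level noise across voxels, so
voxelwise significance behaves like the real analyses (typically empty
after BH) but spatial cluster structure is not realistic. The Gibbs
sampler covers this linear-Gaussian model only — nonlinear trajectories or
non-normal noise would need a different backend. Subtype *discovery* is
out of scope: subtype labels are simulator ground truth or user input.
NIfTI import/export is omitted because no NIfTI-capable R package is
available in the supported dependency set; feature grids use a
binary-array + JSON-sidecar format with delimited-text metadata.
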