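# bagpd — brain age gap analysis of Parkinson's disease progression

Parkinson's disease (PD) progresses at very different speeds in different
people, which complicates clinical management and inflates the sample
sizes of randomized trials. The **brain age gap** (BAG) — the difference
between the brain age estimated from structural MRI gray-matter volumes
and a person's chronological age — is a candidate *prognostic* biomarker:
a single baseline number that flags who is likely to progress quickly.

`bagpd` is an R package for biostatisticians and neuroimaging researchers
that implements this analysis end to end, together with a synthetic
cohort generator with known ground truth (the clinical data such studies
use is access-controlled, so every module here is validated by parameter
recovery on simulated cohorts):

1. **Latent disease time** — a joint mixed-effects model over multiple
   clinical outcomes,

   `y_ijk = x_i' b_k + g_k (t_ijk + d_i) + a0_ik + a1_ik t_ijk + e_ijk`,

   where the per-subject time shift `d_i` (shared across outcomes) aligns
   everyone on a common disease timescale. Fitted by a purpose-built
   blocked Gibbs sampler with split-R-hat convergence checks
   (`fit_ltjmm()`, `latent_times()`, Kendall tau-b validation).
2. **Brain age** — feature smoothing/resampling, lasso / ridge / kernel
   (GP-style) regressors, Cole- and Beheshti-style age-bias corrections,
   cross-validated workflow selection, concordance-correlation retest
   reliability and longitudinal consistency (`train_brain_age()`,
   `fit_bias_correction()`, `apply_bag()`, `select_workflow()`).
3. **Morphometry** — mass-univariate voxel/parcel GLMs between progression
   subtypes with covariates and Benjamini–Hochberg control
   (`groupwise_glm()`, `parcel_means()`, `bh_adjust()`).
4. **Progression statistics** — covariate-adjusted BAG group contrasts,
   mixed-model BAG trajectories, empirical-Bayes outcome slopes, partial
   correlations, and Cox event-free survival with delayed entry on the
   latent timescale plus Schoenfeld PH diagnostics (`compare_bag_groups()`,
   `bag_trajectory()`, `outcome_slopes()`, `bag_correlations()`,
   `cox_fit()`, `ph_check()`).
5. **Trial power** — cognitive composite construction, the Edland
   closed-form sample size for slope treatment effects,

   `n/arm = 2 (z_{1-a/2} + z_pow)^2 (s_slope^2 + s_res^2 / Sxx) / (f mu)^2`,

   Monte Carlo validation, and BAG-percentile prognostic enrichment
   (`composite_score()`, `edland_n()`, `stratified_power()`,
   `validate_power_mc()`).

See `vignettes/bagpd-methods.Rmd` for the models, priors, calibration
choices and limitations.

## Worked example

```r
library(bagpd)

sim <- simulate_cohort(sim_config(), seed = 1)   # 172 HC / 451 PD
fg  <- simulate_features(sim$cohort, sim$truth, grid_geometry(), seed = 1)

s  <- sim$cohort$subjects
hc <- with(fg$scans, subject_id %in% s$subject_id[s$group == "HC"] &
                     !duplicated(subject_id))
# train the S0_R4+LR workflow on HC, fit the Beheshti correction, apply
model <- train_brain_age(subset_grid(fg, hc), fg$scans$age[hc],
                         workflow(0, 4L, "none", "sparse_linear"), seed = 1)
corr  <- fit_bias_correction(predict(model, subset_grid(fg, hc)),
                             fg$scans$age[hc], "beheshti")
bag_hc <- apply_bag(model, corr, subset_grid(fg, hc))
```

Printed output of the full script (seed 1):

```
long_cohort: 623 subjects (172 HC, 451 PD), 34979 observations, 7 outcomes
HC: mean corrected BAG = 0.00 y, corr with age = -0.00
PD: mean corrected BAG = 0.49 y
   fast    slow unknown
   1.59    0.21    0.57
fast vs HC: adjusted dBAG = 1.62 y (p = 0.011)
HC retest CCC = 0.83 (n=21); consistency r = 0.51 (p=0.00062)
```

Reading these numbers: the bias correction forces mean BAG = 0 and zero
age-correlation in the HC it was trained on (an OLS identity — the two
deterministic acceptance targets); PD brains look older than HC brains,
and the excess is concentrated in the fast-progressing subtype, which is
the prognostic signal everything downstream exploits. Retest reliability
(CCC on rescans < 1.5 y apart) and the correlation of brain-age increase
with elapsed time check that BAG behaves like a stable, slowly advancing
quantity.

Enrichment of a simulated 2-year trial (30% slope effect, alpha = 0.1,
80% power), stratifying on the simulator's ground-truth accelerated-aging
score (in this synthetic world most *estimated*-BAG variance is healthy
between-subject variation, so the clean score shows the design effect):

```
  percentile n_subgroup n_total relative_reduction
1          0        451      88              0.000
2         50        225      86              0.023
3         70        135      60              0.318
4         90         45      34              0.614
```

Restricting inclusion to subjects above the 70th/90th BAG percentile cuts
the required sample size by ~32%/61% relative to the unstratified trial.

## CLI

```sh
Rscript -e 'bagpd::run_cli()' simulate --seed 4 --out sim/ --n-pd 120 --n-hc 40
Rscript -e 'bagpd::run_cli()' fit-latent-time --cohort sim/cohort --seed 1 --out fit/
Rscript -e 'bagpd::run_cli()' power --cohort sim/cohort --out power/ \
    --composite moca,updrs1,updrs2,scopa --percentiles 50,70,90
```

(`inst/cli/bagpd` wraps the same dispatcher.)

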