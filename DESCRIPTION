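Package: bagpd
Title: Brain Age Gap Analysis of Parkinson's Disease Progression
Version: 0.1.0
Authors@R:
    person("PD", "Imaging Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the brain age gap (BAG) as a prognostic
    biomarker of Parkinson's disease progression. Provides a synthetic
    longitudinal cohort generator with known ground truth; a latent-time
    joint mixed-effects model (LTJMM) fitted by Gibbs sampling to align
    subjects on a common disease timescale; brain-age estimation workflows
    on voxel-grid gray-matter features with Cole- and Beheshti-style bias
    corrections and reliability metrics; mass-univariate morphometry with
    Benjamini-Hochberg control; covariate-adjusted BAG group comparisons,
    trajectory models, partial correlations and Cox event-free survival on
    the latent timescale; and closed-form (Edland) plus Monte Carlo power
    calculations for BAG-percentile prognostic enrichment of clinical
    trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    glmnet,
    lme4,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
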