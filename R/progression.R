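#' Covariate-adjusted BAG group comparison
#'
#' Pairwise comparison of corrected BAG between two groups via the linear
#' model `BAG ~ group + age + sex (+ latent_time)`. The latent-disease-time
#' covariate is included automatically exactly for the fast-vs-slow subtype
#' contrast (both groups being PD at possibly different disease stages);
#' other contrasts involve HC, for whom latent disease time is undefined.
#'
#' @param bag a `bag_table` restricted to one scan per subject (baseline
#'   rows are selected automatically).
#' @param groups named character vector / factor: group label per subject id
#'   (e.g. `"HC"`, `"fast"`, `"slow"`).
#' @param contrast length-2 character: the two group labels to compare; the
#'   reported coefficient is `contrast[1] - contrast[2]`.
#' @param covars data.frame with one row per subject id (rownames), columns
#'   `age`, `sex`, and `latent_time` where applicable.
#' @return a `comparison_report`: `delta_bag` (adjusted group difference,
#'   years), `p_value`, `n`, `covariates`.
#' @export
compare_bag_groups <- function(bag, groups, contrast, covars) {
  base <- bag[order(bag$subject_id, bag$scan_time), ]
  base <- base[!duplicated(base$subject_id), ]
  g <- groups[base$subject_id]
  keep <- !is.na(g) & g %in% contrast
  d <- base[keep, ]
  g <- factor(g[keep], levels = rev(contrast))  # coefficient = first - second
  if (min(table(g)) < 3) stop_bagpd("each group needs n >= 3")
  cv <- covars[d$subject_id, , drop = FALSE]
  use_latent <- setequal(contrast, c("fast", "slow")) && "latent_time" %in% names(cv)
  covnames <- c("age", "sex", if (use_latent) "latent_time")
  df <- data.frame(bag = d$bag_corrected, group = g, cv[covnames])
  if (anyNA(df)) stop_bagpd("incomplete covariates for the contrast")
  fit <- lm(bag ~ ., data = df)
  if (any(is.na(coef(fit)))) stop_bagpd("rank-deficient design (collinear covariates)")
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  structure(list(contrast = contrast, delta_bag = sm[row, 1],
                 p_value = sm[row, 4], n = nrow(df), covariates = covnames),
            class = "comparison_report")
}

#' Longitudinal BAG trajectory per group
#'
#' Linear mixed-effects model of corrected BAG on time since first scan with
#' fixed and per-subject random intercepts and slopes. Subjects with a
#' single scan cannot inform the slope and are excluded (count logged).
#' P-value and CI for the fixed slope use the normal approximation to the
#' Wald statistic.
#'
#' @param bag a `bag_table` (one group's scans).
#' @return a `trajectory_report`: `slope` (years BAG / year), `p_value`,
#'   `ci` (95%), `n_subjects`, `n_single_scan_excluded`.
#' @export
bag_trajectory <- function(bag) {
  cnt <- table(bag$subject_id)
  multi <- names(cnt)[cnt >= 2]
  excluded <- sum(cnt < 2)
  if (length(multi) < 5) stop_bagpd("need >= 5 subjects with >= 2 scans")
  d <- bag[bag$subject_id %in% multi, ]
  first <- tapply(d$scan_time, d$subject_id, min)
  d$t <- d$scan_time - first[d$subject_id]
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(bag_corrected ~ t + (1 + t | subject_id), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  co <- summary(fit)$coefficients
  slope <- co["t", "Estimate"]; se <- co["t", "Std. Error"]
  z <- slope / se
  structure(list(slope = slope, se = se,
                 p_value = 2 * pnorm(-abs(z)),
                 ci = slope + c(-1, 1) * qnorm(0.975) * se,
                 n_subjects = length(multi),
                 n_single_scan_excluded = excluded),
            class = "trajectory_report")
}

#' Per-subject outcome progression slopes on the latent timescale
#'
#' For each outcome, fits a linear mixed-effects model of the (direction-
#' harmonized, normalized) outcome on latent disease time with fixed and
#' per-subject random intercepts and slopes, and returns the conditional
#' (empirical-Bayes) per-subject slopes: fixed slope + random-slope mode.
#' When the residual variance estimate collapses to ~0 (noise-free data) the
#' per-subject OLS slopes are returned, which are then exact.
#'
#' @param cohort a normalized `long_cohort` (see [normalize_outcomes()]).
#' @param latent latent-time table from [latent_times()].
#' @param min_subjects minimum subjects with >= 2 visits per outcome.
#' @return an `outcome_slope_table` data.frame: subject_id, outcome, slope
#'   (normalized units / latent year), plus the per-outcome fixed slope as
#'   attribute `fixed_slopes`.
#' @export
outcome_slopes <- function(cohort, latent, min_subjects = 20L) {
  obs <- cohort$observations
  if (is.null(obs$value_norm))
    stop_bagpd("cohort not normalized; call normalize_outcomes() first")
  key <- paste(obs$subject_id, obs$time)
  lkey <- paste(latent$subject_id, latent$time)
  obs$latent_time <- latent$latent_time[match(key, lkey)]
  obs <- obs[!is.na(obs$latent_time), ]
  out <- list(); fixed <- c()
  for (k in unique(obs$outcome)) {
    d <- obs[obs$outcome == k, ]
    nv <- table(d$subject_id)
    d <- d[d$subject_id %in% names(nv)[nv >= 2], ]
    if (length(unique(d$subject_id)) < min_subjects)
      stop_bagpd("outcome '%s': fewer than %d subjects with longitudinal coverage",
                 k, min_subjects)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value_norm ~ latent_time + (1 + latent_time | subject_id),
                 data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))))
    if (sigma(fit) < 1e-6) {
      sl <- vapply(split(d, d$subject_id), function(s)
        coef(lm(value_norm ~ latent_time, data = s))[2], 0)
      ids <- names(sl)
      fx <- mean(sl)
    } else {
      re <- lme4::ranef(fit)$subject_id
      fx <- lme4::fixef(fit)[["latent_time"]]
      sl <- fx + re$latent_time
      ids <- rownames(re)
    }
    fixed[k] <- fx
    out[[k]] <- data.frame(subject_id = ids, outcome = k, slope = unname(sl),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("outcome_slope_table", "data.frame")
  attr(res, "fixed_slopes") <- fixed
  res
}

#' Partial Pearson correlation by residualization
#'
#' Residualizes `x` and `y` on the covariates by OLS and correlates the
#' residuals; p-value from the t distribution with `n - k - 2` degrees of
#' freedom (k covariates).
#'
#' @param x,y numeric vectors.
#' @param covars data.frame / matrix of covariates (or `NULL` for plain
#'   Pearson).
#' @return list `r`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covars = NULL) {
  cc <- complete.cases(x, y, if (!is.null(covars)) covars)
  x <- x[cc]; y <- y[cc]
  k <- 0L
  if (!is.null(covars)) {
    Z <- model.matrix(~ ., data = as.data.frame(covars)[cc, , drop = FALSE])
    k <- ncol(Z) - 1L
    x <- lm.fit(Z, x)$residuals
    y <- lm.fit(Z, y)$residuals
  }
  n <- length(x)
  if (n < k + 3) stop_bagpd("need at least covariates + 3 complete cases")
  r <- cor(x, y)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tstat), df), n = n)
}

#' Correlations of baseline BAG with outcomes, BH-corrected within groups
#'
#' Partial correlations of baseline BAG with each target (baseline outcome
#' values or progression slopes), age always as covariate and latent disease
#' time additionally for baseline-outcome targets (disease-severity
#' confound). Benjamini-Hochberg correction is applied within each target
#' family (e.g. clinical / imaging / fluid biomarkers).
#'
#' @param bag_baseline named numeric: corrected baseline BAG per subject id.
#' @param targets data.frame: subject_id, target (name), value, and
#'   `family` (BH family; defaults to one family).
#' @param covars data.frame indexed by subject id with `age` and, for
#'   baseline targets, `latent_time`.
#' @param baseline_targets logical: include latent time as covariate.
#' @return a `correlation_table`: target, family, r, p_raw, p_adjusted, n.
#' @export
bag_correlations <- function(bag_baseline, targets, covars,
                             baseline_targets = FALSE) {
  if (is.null(targets$family)) targets$family <- "all"
  rows <- list()
  for (tg in unique(targets$target)) {
    d <- targets[targets$target == tg, ]
    ids <- d$subject_id
    cv <- covars[ids, c("age", if (baseline_targets) "latent_time"),
                 drop = FALSE]
    pc <- partial_correlation(bag_baseline[ids], d$value, cv)
    rows[[tg]] <- data.frame(target = tg, family = d$family[1], r = pc$r,
                             p_raw = pc$p_value, n = pc$n,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- NA_real_
  for (fam in unique(tab$family)) {
    id <- tab$family == fam
    tab$p_adjusted[id] <- bh_adjust(tab$p_raw[id])
  }
  rownames(tab) <- NULL
  class(tab) <- c("correlation_table", "data.frame")
  attr(tab, "multiplicity_family") <- "within target family (column 'family')"
  tab
}

#' Cox proportional hazards fit with delayed entry
#'
#' Partial-likelihood estimation (Efron ties by default) on the latent
#' disease timescale: subjects enter the risk set at their baseline latent
#' time (left truncation) and exit at event or censoring.
#'
#' @param records data.frame: subject_id, entry_time, exit_time, event, and
#'   covariate columns.
#' @param covariates covariate column names (default: all besides the id /
#'   time / event columns).
#' @param ties `"efron"` or `"breslow"`.
#' @return a `cox_report`: `hr` (hazard ratios), `ci_lower`, `ci_upper`,
#'   `p_values`, `coef`, `loglik`, `n_events`, and the underlying
#'   `survival::coxph` fit.
#' @export
cox_fit <- function(records, covariates = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (anyDuplicated(records$subject_id)) stop_bagpd("duplicate subjects")
  if (sum(records$event) < 1) stop_bagpd("no events in the data")
  if (sum(records$event) < 5) stop_bagpd("need >= 5 events")
  if (any(records$exit_time <= records$entry_time))
    stop_bagpd("exit_time must exceed entry_time for every subject")
  covariates <- covariates %||%
    setdiff(names(records), c("subject_id", "entry_time", "exit_time",
                              "event", "true_score"))
  d <- records
  for (cv in covariates) if (!is.numeric(d[[cv]])) d[[cv]] <- as.numeric(factor(d[[cv]])) - 1
  fml <- as.formula(paste("survival::Surv(entry_time, exit_time, event) ~",
                          paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)
  # monotone-likelihood separation shows up as runaway coefficients
  if (any(abs(coef(fit)) > 15))
    warning("possible monotone-likelihood separation: coefficient(s) diverging")
  sm <- summary(fit)
  structure(list(hr = sm$conf.int[, "exp(coef)"],
                 ci_lower = sm$conf.int[, "lower .95"],
                 ci_upper = sm$conf.int[, "upper .95"],
                 p_values = sm$coefficients[, "Pr(>|z|)"],
                 coef = coef(fit), loglik = fit$loglik[2],
                 n_events = sum(d$event), covariates = covariates,
                 ties = ties, fit = fit, data = d),
            class = "cox_report")
}

#' Proportional-hazards diagnostics (scaled Schoenfeld residuals)
#'
#' Per-covariate score test for a time-varying coefficient against the
#' Kaplan-Meier transform of event time, Benjamini-Hochberg adjusted across
#' covariates, plus the residual-versus-time table for visual inspection.
#'
#' @param report a `cox_report`.
#' @return a `ph_report`: `table` (covariate, chisq, p_raw, p_adjusted),
#'   `residuals` (event time + scaled Schoenfeld residual per covariate).
#' @export
ph_check <- function(report) {
  stopifnot(inherits(report, "cox_report"))
  if (report$n_events < 5) stop_bagpd("too few events for residual tests")
  z <- survival::cox.zph(report$fit, transform = "km")
  tab <- as.data.frame(z$table[report$covariates, , drop = FALSE])
  out <- data.frame(covariate = report$covariates, chisq = tab$chisq,
                    p_raw = tab$p, p_adjusted = bh_adjust(tab$p),
                    stringsAsFactors = FALSE)
  res <- as.data.frame(z$y)
  res$time <- z$time
  structure(list(table = out, residuals = res), class = "ph_report")
}

#' @importFrom stats as.formula sigma
NULL
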