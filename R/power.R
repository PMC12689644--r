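#' Randomized-trial design for slope-difference power calculations
#'
#' Defaults encode a two-year trial with six-monthly visits, 80% power at a
#' two-sided significance level of 0.1, a 30% treatment-induced reduction of
#' the progression rate, and 1:1 allocation.
#'
#' @param visit_times assessment times, years.
#' @param alpha two-sided significance level.
#' @param power_target target power.
#' @param effect_fraction fractional reduction of the mean progression rate.
#' @param one_sided use a one-sided test instead (off by default).
#' @return a `trial_design`.
#' @export
trial_design <- function(visit_times = c(0, 0.5, 1, 1.5, 2), alpha = 0.1,
                         power_target = 0.8, effect_fraction = 0.3,
                         one_sided = FALSE) {
  if (!(alpha > 0 && alpha < 1) || !(power_target > 0 && power_target < 1))
    stop_bagpd("alpha and power_target must lie in (0, 1)")
  if (length(visit_times) < 2) stop_bagpd("need >= 2 visits")
  structure(list(visit_times = sort(visit_times), alpha = alpha,
                 power_target = power_target,
                 effect_fraction = effect_fraction, one_sided = one_sided),
            class = "trial_design")
}

#' Cognitive composite score
#'
#' Averages per-test z-scores computed against the baseline (first-visit)
#' mean and sd of the included subjects, after inverting tests on which
#' higher raw values indicate better function, so that a higher composite
#' always means worse cognition. The baseline composite has mean 0 by
#' construction.
#'
#' @param cohort a `long_cohort`.
#' @param tests character vector of outcome names (typically 4 cognitive
#'   tests); all must be observed at baseline for included subjects.
#' @return data.frame subject_id, time, composite; attribute `scaling`
#'   records the baseline means/sds used.
#' @export
composite_score <- function(cohort, tests) {
  obs <- cohort$observations[cohort$observations$outcome %in% tests, ]
  specs <- cohort$outcomes[tests]
  dirs <- vapply(specs, `[[`, "", "direction")
  first <- tapply(obs$time, obs$subject_id, min)
  obs$is_base <- obs$time == first[obs$subject_id]
  base <- obs[obs$is_base, ]
  have_all <- names(which(tapply(base$outcome, base$subject_id,
                                 function(o) all(tests %in% o))))
  if (!length(have_all)) stop_bagpd("no subject has all tests at baseline")
  obs <- obs[obs$subject_id %in% have_all, ]
  base <- base[base$subject_id %in% have_all, ]
  mu <- tapply(base$value, base$outcome, mean)[tests]
  sdv <- tapply(base$value, base$outcome, sd)[tests]
  if (any(sdv < 1e-12)) stop_bagpd("zero baseline sd for test(s): %s",
                                   paste(tests[sdv < 1e-12], collapse = ", "))
  z <- (obs$value - mu[obs$outcome]) / sdv[obs$outcome]
  z <- ifelse(dirs[obs$outcome] == "higher_better", -z, z)
  agg <- aggregate(z, by = list(subject_id = obs$subject_id, time = obs$time),
                   FUN = mean)
  names(agg)[3] <- "composite"
  agg <- agg[order(agg$subject_id, agg$time), ]
  rownames(agg) <- NULL
  attr(agg, "scaling") <- list(mean = mu, sd = sdv, direction = dirs)
  agg
}

#' Slope variance components for the Edland sample-size formula
#'
#' @param mean_slope mean progression rate (composite units / year).
#' @param slope_var between-subject variance of the rate.
#' @param resid_var residual (within-subject) variance.
#' @return a `slope_components`.
#' @export
slope_components <- function(mean_slope, slope_var, resid_var) {
  if (slope_var < 0 || resid_var < 0) stop_bagpd("variances must be >= 0")
  structure(list(mean_slope = mean_slope, slope_var = slope_var,
                 resid_var = resid_var), class = "slope_components")
}

# mixed model of outcome on time since first visit; components via lme4
estimate_slope_components <- function(values, subject_id, time) {
  d <- data.frame(y = values, id = subject_id, t = time)
  first <- tapply(d$t, d$id, min)
  d$t <- d$t - first[d$id]
  nv <- table(d$id)
  d <- d[d$id %in% names(nv)[nv >= 2], ]
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ t + (1 + t | id), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sv <- vc$vcov[vc$grp == "id" & vc$var1 == "t" & is.na(vc$var2)]
  slope_components(mean_slope = lme4::fixef(fit)[["t"]],
                   slope_var = sv,
                   resid_var = sigma(fit)^2)
}

#' Closed-form (Edland) sample size for a slope treatment effect
#'
#' Per-arm sample size to detect, at two-sided level `alpha` with the target
#' power, a reduction of the mean slope by `effect_fraction` under the
#' random-slope linear mixed model with a fixed visit schedule:
#' \deqn{n/arm = 2 (z_{1-\alpha/2} + z_{pow})^2
#'   (\sigma_s^2 + \sigma_e^2 / \sum_j (t_j - \bar t)^2) / \Delta^2,}
#' with \eqn{\Delta =} `effect_fraction * mean_slope`, rounded up. The
#' accompanying power curve gives the exact normal-approximation power at
#' each per-arm size.
#'
#' @param components a `slope_components` (requires `mean_slope > 0`).
#' @param design a [trial_design()].
#' @param n_grid optional per-arm sizes for the power curve.
#' @return a `power_result`: `n_per_arm`, `n_total`, `power_curve`
#'   (data.frame n_per_arm, power), and the inputs.
#' @export
edland_n <- function(components, design = trial_design(), n_grid = NULL) {
  stopifnot(inherits(components, "slope_components"))
  if (components$mean_slope <= 0)
    stop_bagpd("mean_slope must be > 0 (harmonize outcome direction first)")
  tj <- design$visit_times
  sxx <- sum((tj - mean(tj))^2)
  delta <- design$effect_fraction * components$mean_slope
  if (delta <= 0) {
    warning("zero treatment effect: required n is infinite")
    return(structure(list(n_per_arm = Inf, n_total = Inf,
                          power_curve = NULL, components = components,
                          design = design), class = "power_result"))
  }
  za <- if (design$one_sided) qnorm(1 - design$alpha) else qnorm(1 - design$alpha / 2)
  zb <- qnorm(design$power_target)
  vunit <- components$slope_var + components$resid_var / sxx
  n_arm <- ceiling(2 * (za + zb)^2 * vunit / delta^2)
  if (is.null(n_grid)) n_grid <- unique(pmax(2, round(seq(2, 2 * n_arm, length.out = 60))))
  pw <- pnorm(delta / sqrt(2 * vunit / n_grid) - za)
  structure(list(n_per_arm = n_arm, n_total = 2 * n_arm,
                 power_curve = data.frame(n_per_arm = n_grid, power = pw),
                 sxx = sxx, components = components, design = design),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: n_per_arm = %s (total %s) for %.0f%% power at alpha = %g\n",
              format(x$n_per_arm), format(x$n_total),
              100 * x$design$power_target, x$design$alpha))
  invisible(x)
}

#' BAG-percentile prognostic enrichment
#'
#' For each percentile threshold, restricts the cohort to subjects whose
#' baseline BAG strictly exceeds the empirical percentile, re-estimates the
#' composite's slope components on the subgroup by a random-slope mixed
#' model, and recomputes the Edland sample size. Reductions are relative to
#' the unstratified cohort.
#'
#' @param composite per-visit composite table from [composite_score()].
#' @param bag_baseline named numeric: baseline corrected BAG per subject.
#' @param percentiles thresholds in (0, 100); 0 reproduces the unstratified
#'   result.
#' @param design a [trial_design()].
#' @param min_subgroup minimum subgroup size for component estimation.
#' @return an `enrichment_report`: data.frame `table` (percentile,
#'   n_subgroup, mean_slope, n_per_arm, n_total, relative_reduction) plus
#'   the unstratified `power_result` in `$unstratified`.
#' @export
stratified_power <- function(composite, bag_baseline, percentiles = c(50, 70, 90),
                             design = trial_design(), min_subgroup = 20L) {
  if (any(percentiles < 0 | percentiles >= 100))
    stop_bagpd("percentiles must lie in [0, 100)")
  ids <- intersect(unique(composite$subject_id), names(bag_baseline))
  comp <- composite[composite$subject_id %in% ids, ]
  full <- estimate_slope_components(comp$composite, comp$subject_id, comp$time)
  base_res <- edland_n(full, design)
  rows <- list()
  for (p in percentiles) {
    if (p == 0) {
      sub_ids <- ids
      res <- base_res; sc <- full
    } else {
      thr <- quantile(bag_baseline[ids], p / 100, names = FALSE)
      sub_ids <- ids[bag_baseline[ids] > thr]  # strict: ties excluded
      if (length(sub_ids) < min_subgroup)
        stop_bagpd("subgroup above percentile %g has only %d subjects",
                   p, length(sub_ids))
      d <- comp[comp$subject_id %in% sub_ids, ]
      sc <- estimate_slope_components(d$composite, d$subject_id, d$time)
      res <- edland_n(sc, design)
    }
    rows[[as.character(p)]] <- data.frame(
      percentile = p, n_subgroup = length(sub_ids),
      mean_slope = sc$mean_slope, slope_var = sc$slope_var,
      resid_var = sc$resid_var,
      n_per_arm = res$n_per_arm, n_total = res$n_total,
      relative_reduction = 1 - res$n_total / base_res$n_total)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, unstratified = base_res, design = design),
            class = "enrichment_report")
}

#' Monte Carlo validation of the closed-form power
#'
#' Simulates complete trials from the random-slope model (per-subject slopes
#' normal around the arm mean, residual noise at each scheduled visit),
#' estimates each subject's OLS slope over the schedule and compares arms
#' with a two-sample Welch test (the documented slope-summary fallback to a
#' full mixed model, exact for a shared balanced schedule), returning the
#' rejection fraction at the design's alpha.
#'
#' @param components a `slope_components`.
#' @param design a [trial_design()].
#' @param n total subjects (split 1:1).
#' @param reps Monte Carlo replicates (>= 200).
#' @param seed integer seed.
#' @return empirical power (scalar); attribute `mc_se`.
#' @export
validate_power_mc <- function(components, design = trial_design(), n,
                              reps = 1000L, seed = 1L) {
  if (reps < 200) stop_bagpd("reps must be >= 200")
  tj <- design$visit_times
  J <- length(tj)
  sxx <- sum((tj - mean(tj))^2)
  wj <- (tj - mean(tj)) / sxx            # OLS slope weights
  n1 <- floor(n / 2); n2 <- n - n1
  mu1 <- components$mean_slope
  mu2 <- components$mean_slope * (1 - design$effect_fraction)
  za <- if (design$one_sided) qnorm(1 - design$alpha) else qnorm(1 - design$alpha / 2)
  rej <- with_seed(child_seed(seed, "trial"), {
    vapply(seq_len(reps), function(r) {
      sl1 <- rnorm(n1, mu1, sqrt(components$slope_var))
      sl2 <- rnorm(n2, mu2, sqrt(components$slope_var))
      e1 <- matrix(rnorm(n1 * J, 0, sqrt(components$resid_var)), n1, J)
      e2 <- matrix(rnorm(n2 * J, 0, sqrt(components$resid_var)), n2, J)
      b1 <- sl1 + as.vector(e1 %*% wj)   # per-subject OLS slope estimates
      b2 <- sl2 + as.vector(e2 %*% wj)
      se <- sqrt(var(b1) / n1 + var(b2) / n2)
      zstat <- (mean(b1) - mean(b2)) / se
      if (design$one_sided) zstat > za else abs(zstat) > za
    }, TRUE)
  })
  p <- mean(rej)
  attr(p, "mc_se") <- sqrt(p * (1 - p) / reps)
  p
}

#' Pick the composite's component tests by unstratified sample size
#'
#' Implements the selection rule "the tests with the lowest unstratified
#' sample size": computes the Edland n for each candidate outcome separately
#' (z-scored against baseline) and returns the best `n_tests`.
#'
#' @param cohort a `long_cohort`.
#' @param candidates candidate outcome names.
#' @param design a [trial_design()].
#' @param n_tests number of tests to keep.
#' @return character vector of selected outcome names.
#' @export
select_composite_tests <- function(cohort, candidates, design = trial_design(),
                                   n_tests = 4L) {
  ns <- vapply(candidates, function(tg) {
    cs <- composite_score(cohort, tg)
    sc <- estimate_slope_components(cs$composite, cs$subject_id, cs$time)
    if (sc$mean_slope <= 0) return(Inf)
    edland_n(sc, design)$n_total
  }, 0)
  names(sort(ns))[seq_len(min(n_tests, length(candidates)))]
}
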