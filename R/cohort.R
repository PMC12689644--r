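#' Outcome specification
#'
#' Describes one clinical outcome: its theoretical score range and the
#' direction in which larger values indicate worse disease. Slopes and noise
#' are expressed on the min-max normalized (0-1) scale used throughout the
#' latent-time model.
#'
#' @param name outcome name (e.g. `"updrs3"`).
#' @param theoretical_min,theoretical_max theoretical score range, in raw
#'   score units.
#' @param direction `"higher_worse"` or `"higher_better"` (the latter, e.g. a
#'   cognitive screening score, is inverted during normalization).
#' @param mean_slope cohort-level progression rate, normalized units / year,
#'   on the harmonized (higher = worse) scale; must be positive.
#' @param noise_sd residual measurement noise sd, normalized units.
#' @return an `outcome_spec` object.
#' @export
outcome_spec <- function(name, theoretical_min, theoretical_max,
                         direction = c("higher_worse", "higher_better"),
                         mean_slope, noise_sd) {
  direction <- match.arg(direction)
  if (!(theoretical_min < theoretical_max))
    stop_bagpd("outcome '%s': theoretical_min must be < theoretical_max", name)
  if (mean_slope <= 0)
    stop_bagpd("outcome '%s': mean_slope must be > 0 after direction harmonization", name)
  if (noise_sd < 0) stop_bagpd("outcome '%s': noise_sd must be >= 0", name)
  structure(list(name = name, theoretical_min = theoretical_min,
                 theoretical_max = theoretical_max, direction = direction,
                 mean_slope = mean_slope, noise_sd = noise_sd),
            class = "outcome_spec")
}

#' Default outcome panel
#'
#' Seven motor and non-motor outcomes mimicking the panel typically used for
#' latent-time alignment in early PD (MDS-UPDRS parts I-IV, a postural
#' instability / gait score, a cognitive screen, and an autonomic-dysfunction
#' scale). Slopes are on the normalized scale; e.g. 0.03/year on a 0-132
#' motor scale corresponds to about 4 raw points per year.
#'
#' @return named list of [outcome_spec()] objects.
#' @export
default_outcomes <- function() {
  specs <- list(
    outcome_spec("updrs1", 0, 52,  "higher_worse",  mean_slope = 0.030, noise_sd = 0.030),
    outcome_spec("updrs2", 0, 52,  "higher_worse",  mean_slope = 0.035, noise_sd = 0.030),
    outcome_spec("updrs3", 0, 132, "higher_worse",  mean_slope = 0.030, noise_sd = 0.025),
    outcome_spec("updrs4", 0, 24,  "higher_worse",  mean_slope = 0.020, noise_sd = 0.030),
    outcome_spec("pigd",   0, 20,  "higher_worse",  mean_slope = 0.025, noise_sd = 0.030),
    outcome_spec("moca",   0, 30,  "higher_better", mean_slope = 0.020, noise_sd = 0.025),
    outcome_spec("scopa",  0, 69,  "higher_worse",  mean_slope = 0.025, noise_sd = 0.030))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Simulation configuration
#'
#' The stated world of the generator. Defaults follow the cohort structure the
#' downstream analyses assume: a two-subtype PD mixture (fast 14.6%, slow
#' 65.4%, unknown 20.0%), mean-zero normal per-subject time shifts
#' (sd 1 year), diagnosis within the two years preceding baseline, 6-month
#' visit spacing with geometric dropout.
#'
#' @param n_hc,n_pd numbers of healthy controls and people with PD.
#' @param outcomes named list of [outcome_spec()]s.
#' @param subtype_probs probabilities of (fast, slow, unknown) within PD;
#'   must sum to 1.
#' @param slope_multipliers subtype multipliers on progression rates; the
#'   defaults are centred so the mixture-weighted mean is ~1 and the cohort
#'   mean slope stays interpretable as `mean_slope`.
#' @param delta_sd sd of the per-subject time shift delta (years).
#' @param alpha0_sd,alpha1_sd sds of random intercepts (normalized units) and
#'   random slopes (normalized units / year).
#' @param age_range baseline age range (years).
#' @param baseline_level mean normalized severity at diagnosis (intercept).
#' @param beta_age,beta_sex covariate effects of age-at-diagnosis (per decade
#'   from 60) and male sex on the normalized outcome level.
#' @param visit_spacing years between scheduled visits.
#' @param dropout_prob per-visit probability of dropping out afterwards.
#' @param max_followup administrative end of follow-up, years.
#' @param clamp_values clamp generated values into the theoretical range
#'   (flagged); if `FALSE`, out-of-range values are kept.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_hc = 172, n_pd = 451,
                       outcomes = default_outcomes(),
                       subtype_probs = c(fast = 0.146, slow = 0.654, unknown = 0.200),
                       slope_multipliers = c(fast = 2.0, slow = 0.78, unknown = 1.0),
                       delta_sd = 1.0,
                       alpha0_sd = 0.03, alpha1_sd = 0.008,
                       age_range = c(40, 85),
                       baseline_level = 0.15,
                       beta_age = 0.02, beta_sex = 0.01,
                       visit_spacing = 0.5, dropout_prob = 0.10,
                       max_followup = 8,
                       clamp_values = TRUE) {
  if (abs(sum(subtype_probs) - 1) > 1e-8)
    stop_bagpd("subtype mixture must sum to 1 over {fast, slow, unknown}")
  if (delta_sd < 0 || alpha0_sd < 0 || alpha1_sd < 0)
    stop_bagpd("variance components must be non-negative")
  if (any(vapply(outcomes, `[[`, 0, "noise_sd") < 0))
    stop_bagpd("outcome noise sds must be non-negative")
  structure(list(n_hc = n_hc, n_pd = n_pd, outcomes = outcomes,
                 subtype_probs = subtype_probs,
                 slope_multipliers = slope_multipliers,
                 delta_sd = delta_sd, alpha0_sd = alpha0_sd,
                 alpha1_sd = alpha1_sd, age_range = age_range,
                 baseline_level = baseline_level, beta_age = beta_age,
                 beta_sex = beta_sex, visit_spacing = visit_spacing,
                 dropout_prob = dropout_prob, max_followup = max_followup,
                 clamp_values = clamp_values),
            class = "sim_config")
}

# Visit times since diagnosis (PD) or enrollment (HC). PD enter the study
# 0-2 years after diagnosis; visits every `spacing` years with geometric
# dropout and an administrative follow-up cap.
make_visits <- function(entry, spacing, dropout_prob, max_followup) {
  n_sched <- floor((max_followup - entry) / spacing)
  n_kept <- min(rgeom(1, dropout_prob), n_sched)
  entry + spacing * (0:max(n_kept, 1))
}

#' Simulate a longitudinal PD/HC cohort with known ground truth
#'
#' Draws a cohort whose PD observations follow, exactly, the latent-time
#' joint mixed-effects generative model
#' `y = x'beta_k + gamma_k (t + delta_i) + a0_ik + a1_ik t + eps`:
#' a per-subject time shift `delta_i` shared across outcomes, outcome-specific
#' fixed slopes, mean-zero normal random intercepts/slopes and normal noise.
#' HC observations have no disease slope and no time shift. Subtype membership
#' scales a subject's progression rate through the mean of the random slope.
#'
#' Values are generated on the normalized 0-1 scale, then mapped back to raw
#' score units (with direction-appropriate inversion) and optionally clamped
#' into the theoretical range; the clamped fraction is recorded.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical `(config, seed)` reproduce identical
#'   output.
#' @return list with elements `cohort` (a `long_cohort`: `$subjects`,
#'   `$observations`) and `truth` (a `ground_truth` holding every generative
#'   parameter: `delta`, `gamma`, `beta`, random effects, clamped fraction).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(seed, "cohort"))

  n <- config$n_hc + config$n_pd
  group <- rep(c("HC", "PD"), c(config$n_hc, config$n_pd))
  subject_id <- sprintf("S%04d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.63, 0.37))
  age0 <- runif(n, config$age_range[1], config$age_range[2])

  subtype <- rep(NA_character_, n)
  pd <- group == "PD"
  subtype[pd] <- sample(names(config$subtype_probs), config$n_pd,
                        replace = TRUE, prob = config$subtype_probs)
  mult <- rep(NA_real_, n)
  mult[pd] <- config$slope_multipliers[subtype[pd]]

  delta <- rep(0, n)
  delta[pd] <- rnorm(config$n_pd, 0, config$delta_sd)

  # time since diagnosis at study entry: diagnosis within 2 years before
  # baseline for PD; HC measured from enrollment
  entry <- ifelse(pd, runif(n, 0, 2), 0)

  subjects <- data.frame(
    subject_id = subject_id, group = group, subtype = subtype, sex = sex,
    age_at_baseline = age0 + entry,
    age_at_diagnosis = age0,
    entry_time = entry,
    true_time_shift = ifelse(pd, delta, NA_real_),
    true_slope_multiplier = mult,
    stringsAsFactors = FALSE)

  specs <- config$outcomes
  K <- length(specs)
  kn <- names(specs)
  gamma <- vapply(specs, `[[`, 0, "mean_slope")
  sigma_eps <- vapply(specs, `[[`, 0, "noise_sd")

  # covariate effects on the normalized scale (x: age at diagnosis, sex)
  beta <- cbind(intercept = rep(config$baseline_level, K),
                age_c = rep(config$beta_age, K),
                sexM = rep(config$beta_sex, K))
  rownames(beta) <- kn

  visits <- lapply(seq_len(n), function(i)
    make_visits(entry[i], config$visit_spacing, config$dropout_prob,
                config$max_followup))

  a0 <- matrix(rnorm(n * K, 0, config$alpha0_sd), n, K, dimnames = list(subject_id, kn))
  # subtype shifts the *mean* of the random slope: fast progressors tilt all
  # outcome trajectories upward together
  a1_mean <- outer(ifelse(pd, mult - 1, 0), gamma)   # HC have no disease slope at all
  a1 <- a1_mean + matrix(rnorm(n * K, 0, config$alpha1_sd), n, K,
                         dimnames = list(subject_id, kn))

  obs <- vector("list", n)
  for (i in seq_len(n)) {
    t <- visits[[i]]
    x_age <- (age0[i] - 60) / 10
    x_sex <- as.numeric(sex[i] == "M")
    vals <- matrix(NA_real_, length(t), K)
    for (k in seq_len(K)) {
      mu <- beta[k, 1] + beta[k, 2] * x_age + beta[k, 3] * x_sex +
        (if (pd[i]) gamma[k] * (t + delta[i]) else 0) +
        a0[i, k] + a1[i, k] * t
      vals[, k] <- mu + rnorm(length(t), 0, sigma_eps[k])
    }
    obs[[i]] <- data.frame(
      subject_id = subject_id[i],
      time = rep(t, K),
      outcome = rep(kn, each = length(t)),
      value_norm = as.vector(vals), stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)

  # map normalized values to raw score units; invert higher_better outcomes
  rngs <- vapply(specs, function(s) c(s$theoretical_min, s$theoretical_max),
                 numeric(2))
  dirs <- vapply(specs, `[[`, "", "direction")
  idx <- match(obs$outcome, kn)
  vnorm <- obs$value_norm
  vn <- ifelse(dirs[idx] == "higher_better", 1 - vnorm, vnorm)
  raw <- rngs[1, idx] + vn * (rngs[2, idx] - rngs[1, idx])
  out_of_range <- raw < rngs[1, idx] | raw > rngs[2, idx]
  clamped_fraction <- mean(out_of_range)
  if (config$clamp_values) raw <- clamp(raw, rngs[1, idx], rngs[2, idx])
  obs$value <- raw
  obs$clamped <- out_of_range & config$clamp_values
  obs$value_norm <- NULL

  cohort <- structure(list(subjects = subjects,
                           observations = obs[, c("subject_id", "time",
                                                  "outcome", "value", "clamped")],
                           outcomes = specs),
                      class = "long_cohort")
  truth <- structure(list(config = config, seed = seed,
                          delta = setNames(delta[pd], subject_id[pd]),
                          gamma = gamma, beta = beta,
                          sigma_eps = sigma_eps,
                          alpha0 = a0, alpha1 = a1,
                          slope_multiplier = setNames(mult[pd], subject_id[pd]),
                          clamped_fraction = clamped_fraction),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.long_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("long_cohort: %d subjects (%d HC, %d PD), %d observations, %d outcomes\n",
              nrow(s), sum(s$group == "HC"), sum(s$group == "PD"),
              nrow(x$observations), length(x$outcomes)))
  invisible(x)
}

#' Write / read a cohort as tidy delimited text
#'
#' Two tab-separated files: `<stem>_subjects.tsv` and
#' `<stem>_observations.tsv`.
#'
#' @param cohort a `long_cohort`.
#' @param stem path stem (without extension).
#' @return `write_cohort`: the stem, invisibly. `read_cohort`: a
#'   `long_cohort` (outcome specs restored from an accompanying JSON sidecar).
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "long_cohort"))
  data.table::fwrite(cohort$subjects, paste0(stem, "_subjects.tsv"), sep = "\t")
  data.table::fwrite(cohort$observations, paste0(stem, "_observations.tsv"), sep = "\t")
  specs <- lapply(cohort$outcomes, unclass)
  jsonlite::write_json(specs, paste0(stem, "_outcomes.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  subjects <- as.data.frame(data.table::fread(paste0(stem, "_subjects.tsv")))
  observations <- as.data.frame(data.table::fread(paste0(stem, "_observations.tsv")))
  sj <- jsonlite::read_json(paste0(stem, "_outcomes.json"))
  outcomes <- lapply(sj, function(s)
    outcome_spec(s$name, s$theoretical_min, s$theoretical_max, s$direction,
                 s$mean_slope, s$noise_sd))
  names(outcomes) <- vapply(outcomes, `[[`, "", "name")
  structure(list(subjects = subjects, observations = observations,
                 outcomes = outcomes), class = "long_cohort")
}
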