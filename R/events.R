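#' Simulate time-to-event outcomes under proportional hazards
#'
#' Event times are drawn from an exponential proportional-hazards model with
#' covariates age at baseline, sex, and the subject's ground-truth
#' accelerated-aging score (the quantity a brain-age model estimates as BAG),
#' then censored administratively at the end of follow-up. Intended as the
#' generative counterpart of the event-free survival analysis (e.g. onset of
#' mild cognitive impairment).
#'
#' @param cohort a `long_cohort` (PD subjects are used).
#' @param truth matching `ground_truth`.
#' @param beta_bag log hazard ratio per year of accelerated-aging score.
#' @param seed integer seed.
#' @param baseline_hazard events / year at covariate reference (> 0).
#' @param beta_age,beta_sex log hazard ratios per decade of age from 60 and
#'   for male sex.
#' @param followup administrative censoring time, years.
#' @param true_score optional per-subject score overriding the default
#'   (named by subject id).
#' @return an `event_table` data.frame: subject_id, entry_time, exit_time,
#'   event, age_at_baseline, sex, true_score.
#' @export
simulate_events <- function(cohort, truth, beta_bag = log(1.04), seed = 1L,
                            baseline_hazard = 0.08, beta_age = 0.2,
                            beta_sex = 0.1, followup = 8,
                            true_score = NULL) {
  if (baseline_hazard <= 0) stop_bagpd("baseline hazard must be > 0")
  s <- cohort$subjects[cohort$subjects$group == "PD", ]
  set.seed(child_seed(seed, "events"))
  if (is.null(true_score)) {
    # accelerated-aging score: subtype acceleration x latent disease stage,
    # in years of excess brain age at baseline
    mult <- truth$slope_multiplier[s$subject_id]
    delta <- truth$delta[s$subject_id]
    true_score <- 2 * (mult - 1) + pmax(0, s$entry_time + delta)
  } else true_score <- true_score[s$subject_id]
  lp <- beta_age * (s$age_at_baseline - 60) / 10 +
    beta_sex * (s$sex == "M") + beta_bag * true_score
  rate <- baseline_hazard * exp(lp)
  tt <- rexp(nrow(s), rate)
  event <- tt <= followup
  out <- data.frame(subject_id = s$subject_id,
                    entry_time = 0,
                    exit_time = pmin(tt, followup),
                    event = event,
                    age_at_baseline = s$age_at_baseline,
                    sex = s$sex,
                    true_score = unname(true_score),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}
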