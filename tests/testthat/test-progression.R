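make_bag_table <- function(subject_id, scan_time, bag, age = 65, sex = NULL) {
  d <- data.frame(subject_id = subject_id, scan_time = scan_time,
                  chronological_age = age + scan_time,
                  brain_age_raw = age + scan_time + bag,
                  brain_age_corrected = age + scan_time + bag,
                  bag_corrected = bag, stringsAsFactors = FALSE)
  class(d) <- c("bag_table", "data.frame")
  d
}

test_that("group comparison recovers a constructed +3y offset and nulls", {
  set.seed(21)
  n <- 300
  ids <- sprintf("s%03d", 1:n)
  grp <- setNames(rep(c("HC", "fast"), each = n / 2), ids)
  bag <- rnorm(n, 0, 2) + ifelse(grp == "fast", 3, 0)
  bt <- make_bag_table(ids, 0, bag)
  covars <- data.frame(age = rnorm(n, 63, 8), sex = sample(c("M", "F"), n, TRUE),
                       row.names = ids)
  rep <- compare_bag_groups(bt, grp, c("fast", "HC"), covars)
  expect_equal(rep$delta_bag, 3, tolerance = 3 * 2 / sqrt(n / 4))
  expect_lt(rep$p_value, 1e-6)
  expect_false("latent_time" %in% rep$covariates)

  # same-distribution null
  grp0 <- setNames(rep(c("slow", "fast"), each = n / 2), ids)
  bag0 <- rnorm(n, 1, 2)
  bt0 <- make_bag_table(ids, 0, bag0)
  covars$latent_time <- rnorm(n)
  rep0 <- compare_bag_groups(bt0, grp0, c("fast", "slow"), covars)
  expect_lt(abs(rep0$delta_bag), 1)
  expect_true("latent_time" %in% rep0$covariates)  # auto-added for fast-vs-slow

  # collinear covariate -> rank-deficiency error
  expect_error(compare_bag_groups(bt, grp, c("fast", "HC"),
                                  transform(covars, sex = age)),
               "rank-deficient")
})

test_that("BAG trajectories: constructed slope recovered, constants flat", {
  set.seed(31)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  rows <- do.call(rbind, lapply(ids, function(id) {
    t <- c(0, 1.5, 3)
    data.frame(subject_id = id, scan_time = t,
               bag = rnorm(1, 0, 1.5) + 0.4 * t + rnorm(3, 0, 0.3))
  }))
  bt <- make_bag_table(rows$subject_id, rows$scan_time, rows$bag)
  rep <- bag_trajectory(bt)
  expect_true(rep$ci[1] <= 0.4 && 0.4 <= rep$ci[2])
  expect_lt(rep$p_value, 0.001)

  # constant per-subject BAG -> slope ~ 0; single-scan subjects logged
  rows2 <- do.call(rbind, lapply(ids, function(id)
    data.frame(subject_id = id, scan_time = c(0, 2), bag = rnorm(1))))
  extra <- data.frame(subject_id = "lonely", scan_time = 0, bag = 0)
  bt2 <- make_bag_table(c(rows2$subject_id, extra$subject_id),
                        c(rows2$scan_time, extra$scan_time),
                        c(rows2$bag, extra$bag))
  rep2 <- bag_trajectory(bt2)
  expect_lt(abs(rep2$slope), 0.1)
  expect_equal(rep2$n_single_scan_excluded, 1)
  expect_error(bag_trajectory(bt2[bt2$scan_time == 0, ]), ">= 5 subjects")
})

test_that("outcome slopes are exact on noise-free data and shrink with visits", {
  # noise-free linear trajectories: slopes equal generative slopes
  cfg <- noisefree_config(n_hc = 2, n_pd = 25)
  sim <- simulate_cohort(cfg, seed = 12)
  co <- normalize_outcomes(sim$cohort, out_of_range = "clamp")
  pd_ids <- co$subjects$subject_id[co$subjects$group == "PD"]
  lt <- unique(co$observations[co$observations$subject_id %in% pd_ids,
                               c("subject_id", "time")])
  lt$latent_time <- lt$time  # delta = 0 world
  st <- outcome_slopes(co, lt)
  g <- sim$truth$gamma[st$outcome]
  expect_equal(st$slope, unname(g), tolerance = 1e-6)

  # shrinkage: 2-visit subjects pulled harder toward the fixed slope
  set.seed(44)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  nv <- rep(c(2L, 8L), each = n / 2)
  true_sl <- rnorm(n, 0.5, 0.4)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- if (nv[i] == 2L) c(0, 1) else seq(0, 4, length.out = nv[i])
    data.frame(subject_id = ids[i], time = t, outcome = "comp",
               value = 5 + true_sl[i] * t + rnorm(nv[i], 0, 0.6),
               clamped = FALSE)
  }))
  co2 <- structure(list(
    subjects = data.frame(subject_id = ids, group = "PD"),
    observations = obs,
    outcomes = list(comp = outcome_spec("comp", 0, 100, "higher_worse", 0.02, 0.01))),
    class = "long_cohort")
  co2 <- normalize_outcomes(co2)
  lt2 <- unique(obs[, c("subject_id", "time")])
  lt2$latent_time <- lt2$time
  st2 <- outcome_slopes(co2, lt2, min_subjects = 10)
  fx <- attr(st2, "fixed_slopes")[["comp"]]
  dev <- abs(st2$slope - fx)
  sparse <- st2$subject_id %in% ids[nv == 2]
  expect_lt(mean(dev[sparse]), mean(dev[!sparse]))
})

test_that("partial correlation equals both oracles and handles nulls", {
  set.seed(9)
  # n = 6 fixture with one covariate, residualization oracle by hand
  x <- c(1, 3, 2, 5, 4, 6); y <- c(2, 1, 4, 3, 6, 5); z <- c(1, 2, 3, 4, 5, 6)
  pc <- partial_correlation(x, y, data.frame(z = z))
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$r, oracle_partial_r(x, y, z), tolerance = 1e-10)
  # inverse-correlation-matrix oracle on random fixtures
  for (r in 1:10) {
    n <- sample(8:30, 1)
    Z <- matrix(rnorm(2 * n), n)
    a <- rnorm(n) + Z %*% c(1, -1)
    b <- rnorm(n) + Z %*% c(0.5, 0.5)
    expect_equal(partial_correlation(a, b, as.data.frame(Z))$r,
                 oracle_partial_r(a, b, Z), tolerance = 1e-10)
  }
  expect_error(partial_correlation(1:4, 1:4, data.frame(z = c(1, 2, 1, 3), w = 1:4)),
               "complete cases")
})

test_that("bag_correlations separates loading from non-loading targets", {
  set.seed(61)
  n <- 250
  ids <- sprintf("s%03d", 1:n)
  u <- rnorm(n, 0, 3)          # accelerated-aging factor = BAG signal
  bag <- setNames(u + rnorm(n, 0, 1), ids)
  cog_slope <- 0.3 * u + rnorm(n, 0, 1)   # cognition loads on the factor
  mot_slope <- rnorm(n, 0, 1)             # motor progression does not
  targets <- rbind(
    data.frame(subject_id = ids, target = "cog_slope", value = cog_slope,
               family = "clinical"),
    data.frame(subject_id = ids, target = "motor_slope", value = mot_slope,
               family = "clinical"))
  covars <- data.frame(age = rnorm(n, 63, 8), row.names = ids)
  tab <- bag_correlations(bag, targets, covars)
  expect_lt(tab$p_adjusted[tab$target == "cog_slope"], 0.001)
  expect_gt(tab$p_adjusted[tab$target == "motor_slope"], 0.05)
  expect_true(all(tab$p_adjusted >= tab$p_raw - 1e-15))
  expect_match(attr(tab, "multiplicity_family"), "family")
})

test_that("cox partial likelihood matches risk-set enumeration on a fixture", {
  rec <- data.frame(subject_id = sprintf("s%d", 1:4),
                    entry_time = 0, exit_time = c(1, 2, 3, 4),
                    event = c(TRUE, TRUE, TRUE, FALSE),
                    x = c(1, 0, 1, 0))
  fit <- cox_fit(rbind(rec, within(rec, {
    subject_id <- paste0(subject_id, "b"); exit_time <- exit_time + 0.5
  })), covariates = "x")
  X <- matrix(fit$data$x, ncol = 1)
  ll <- oracle_cox_loglik(fit$coef, fit$data$entry_time, fit$data$exit_time,
                          fit$data$event, X)
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  # the score vanishes at the maximum (finite-difference check on the oracle)
  eps <- 1e-6
  d1 <- oracle_cox_loglik(fit$coef + eps, fit$data$entry_time,
                          fit$data$exit_time, fit$data$event, X)
  d2 <- oracle_cox_loglik(fit$coef - eps, fit$data$entry_time,
                          fit$data$exit_time, fit$data$event, X)
  expect_lt(abs((d1 - d2) / (2 * eps)), 1e-4)
})

test_that("delayed entry is inert at entry_time = 0 and null HR ~ 1", {
  set.seed(71)
  n <- 400
  rec <- data.frame(subject_id = sprintf("s%03d", 1:n), entry_time = 0,
                    exit_time = rexp(n, 0.2), event = TRUE,
                    x = rep(0:1, n / 2))
  rec$event <- rec$exit_time < 6
  rec$exit_time <- pmin(rec$exit_time, 6)
  f1 <- cox_fit(rec, "x")
  expect_gt(f1$hr[[1]], 0.8); expect_lt(f1$hr[[1]], 1.25)
  # shifting everyone's entry to a common positive time with exits shifted too
  rec2 <- rec
  rec2$entry_time <- 0  # baseline comparison against a left-truncated copy
  keep <- rec$exit_time > 0.5
  rec3 <- rec[keep, ]; rec3$entry_time <- 0.5
  f3 <- cox_fit(rec3, "x")
  rec4 <- rec[keep, ]
  f4 <- cox_fit(rec4, "x")  # without truncation, same risk sets after 0.5
  expect_equal(f3$coef, f4$coef, tolerance = 1e-8)
  expect_error(cox_fit(rec[0, ], "x"), "no events")
})

test_that("PH tests keep size under a proportional-hazards world", {
  set.seed(91)
  n <- 250
  ok <- vapply(1:100, function(r) {
    x <- rnorm(n)
    t <- rexp(n, 0.25 * exp(0.4 * x))
    rec <- data.frame(subject_id = seq_len(n), entry_time = 0,
                      exit_time = pmin(t, 8), event = t < 8, x = x)
    all(ph_check(cox_fit(rec, "x"))$table$p_adjusted > 0.05)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("PH check accepts proportional data and flags a built-in violation", {
  set.seed(81)
  n <- 1500
  x <- rep(0:1, n / 2)
  # violation: effect reverses sign at the median event time
  t1 <- rexp(n, 0.3 * exp(0.8 * x))
  flip <- t1 > median(t1)
  t <- ifelse(flip, median(t1) + rexp(n, 0.3 * exp(-1.2 * x)), t1)
  rec <- data.frame(subject_id = seq_len(n), entry_time = 0,
                    exit_time = t, event = TRUE, x = x)
  ph <- ph_check(cox_fit(rec, "x"))
  expect_equal(nrow(ph$table), 1)       # one row per covariate
  expect_lt(ph$table$p_adjusted, 0.05)
  expect_true(all(c("time", "x") %in% names(ph$residuals)))
})
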