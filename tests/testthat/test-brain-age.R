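test_that("gaussian smoothing: identity, constants, and the impulse oracle", {
  arr <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  expect_identical(gaussian_smooth(arr, 0), arr)
  cst <- array(7, c(6, 6, 6))
  expect_equal(gaussian_smooth(cst, 11, c(1, 1, 1)), cst, tolerance = 1e-12)

  # unit impulse vs direct convolution; interior support
  d <- c(17, 17, 17)
  imp <- array(0, d); imp[9, 9, 9] <- 1
  sm <- gaussian_smooth(imp, 4, c(1, 1, 1))
  expect_equal(sm, oracle_gauss_conv(imp, 4 / 2.3548200450309493),
               tolerance = 1e-10)
  # mass preservation needs the kernel support well inside the grid
  sm2 <- gaussian_smooth(imp, 2, c(1, 1, 1))
  expect_equal(sum(sm2), 1, tolerance = 1e-10)
  expect_error(gaussian_smooth(imp, -1), "fwhm")
})

test_that("smooth_and_resample contracts: identity, constants, errors", {
  sim <- small_world(n_hc = 4, n_pd = 2, seed = 1)
  g <- grid_geometry(c(8, 8, 8), brain_mask = array(TRUE, c(8, 8, 8)))
  fg <- simulate_features(sim$cohort, sim$truth, g, seed = 1)
  expect_identical(smooth_and_resample(fg, 0, 1L), fg)
  fg2 <- fg; fg2$data[] <- 3.14
  out <- smooth_and_resample(fg2, 13, 2L)
  expect_equal(unique(round(as.vector(out$data), 10)), 3.14)
  expect_identical(out$geometry$dims, c(4L, 4L, 4L))
  expect_equal(out$geometry$spacing, fg$geometry$spacing * 2)
  expect_error(smooth_and_resample(fg, -1, 1L), "fwhm")
  expect_error(smooth_and_resample(fg, 0, 0L), "factor")
})

test_that("named workflows carry the advertised pipeline stages", {
  wfs <- default_workflows()
  expect_setequal(vapply(wfs, `[[`, "", "name"),
                  c("S4_R4+GPR", "S4_R4+PCA+GPR", "S0_R4+LR"))
  lr <- wfs[[3]]
  expect_equal(lr$smoothing_fwhm, 0)
  expect_equal(lr$resample_factor, 4L)
  expect_equal(lr$regressor, "sparse_linear")
})

test_that("constant training labels yield a constant predictor", {
  sim <- small_world(n_hc = 30, n_pd = 2, seed = 2)
  fg <- simulate_features(sim$cohort, sim$truth, grid_geometry(c(8, 8, 8)),
                          seed = 2, p_longitudinal = 0)
  g <- hc_baseline_grid(sim, fg)
  m <- train_brain_age(g, rep(63, nrow(g$data)), workflow(), seed = 1)
  expect_equal(predict(m, g), rep(63, nrow(g$data)))
})

test_that("bias corrections reproduce hand-computed OLS fixtures", {
  # beheshti: ages (50,60,70), BAG (2,0,-2) -> BAG = 12 - 0.2 age, residual 0
  pred <- c(50, 60, 70) + c(2, 0, -2)
  bc <- fit_bias_correction(rep(pred, 4), rep(c(50, 60, 70), 4), "beheshti")
  expect_equal(bc$intercept, 12, tolerance = 1e-10)
  expect_equal(bc$slope, -0.2, tolerance = 1e-10)
  expect_equal(bagpd:::correct_bag(bc, pred, c(50, 60, 70)), c(0, 0, 0),
               tolerance = 1e-10)
  # cole: ages (50,60,70), pred (55,60,65) -> a = 30, b = 0.5
  bc2 <- fit_bias_correction(rep(c(55, 60, 65), 4), rep(c(50, 60, 70), 4), "cole")
  expect_equal(bc2$intercept, 30, tolerance = 1e-10)
  expect_equal(bc2$slope, 0.5, tolerance = 1e-10)
  expect_equal(bagpd:::correct_bag(bc2, c(55, 60, 65), c(50, 60, 70)),
               c(0, 0, 0), tolerance = 1e-10)
  # pred == chron: both corrections act as the identity
  ch <- seq(45, 80, length.out = 12)
  for (m in c("cole", "beheshti"))
    expect_equal(bagpd:::correct_bag(fit_bias_correction(ch, ch, m), ch, ch),
                 rep(0, 12), tolerance = 1e-10)
  expect_error(fit_bias_correction(1:5, 1:5), ">= 10")
  expect_error(fit_bias_correction(rep(1, 12), rep(2, 12), "cole"), "variance")
})

test_that("correction invariances: beheshti to shifts, cole to affine maps", {
  set.seed(4)
  ch <- runif(40, 45, 85)
  pred <- ch + rnorm(40, 0, 3) + 0.2 * (ch - 65)
  b1 <- bagpd:::correct_bag(fit_bias_correction(pred, ch, "beheshti"), pred, ch)
  b2 <- bagpd:::correct_bag(fit_bias_correction(pred + 11, ch, "beheshti"),
                            pred + 11, ch)
  expect_equal(b1, b2, tolerance = 1e-10)
  aff <- 3 + 1.7 * pred
  c1 <- bagpd:::correct_bag(fit_bias_correction(pred, ch, "cole"), pred, ch)
  c2 <- bagpd:::correct_bag(fit_bias_correction(aff, ch, "cole"), aff, ch)
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("applying a correction to its own training HC zeroes mean and age-trend", {
  sim <- simulate_cohort(sim_config(n_hc = 120, n_pd = 2), seed = 14)
  fg <- simulate_features(sim$cohort, sim$truth, grid_geometry(c(10, 10, 10)),
                          seed = 14, p_longitudinal = 0)
  g <- hc_baseline_grid(sim, fg)
  ages <- g$scans$age
  m <- train_brain_age(g, ages, workflow(0, 2L, "none", "ridge"), seed = 1)
  for (method in c("beheshti", "cole")) {
    bc <- fit_bias_correction(predict(m, g), ages, method)
    bag <- apply_bag(m, bc, g, ages)
    expect_equal(mean(bag$bag_corrected), 0, tolerance = 1e-8)
    expect_equal(cor(bag$bag_corrected, ages), 0, tolerance = 1e-8)
    expect_equal(bag$bag_corrected,
                 bag$brain_age_corrected - bag$chronological_age,
                 tolerance = 1e-12)
  }
  expect_error(apply_bag(m, bc, g, ages[-1]), "mismatch")
})

test_that("workflow selection returns the argmin and is deterministic", {
  sim <- simulate_cohort(sim_config(n_hc = 80, n_pd = 2), seed = 23)
  fg <- simulate_features(sim$cohort, sim$truth, grid_geometry(c(10, 10, 10)),
                          seed = 23, p_longitudinal = 0)
  g <- hc_baseline_grid(sim, fg)
  ages <- g$scans$age
  wfs <- list(workflow(0, 2L, "none", "ridge"),
              workflow(0, 2L, "none", "kernel_gp"))
  rep1 <- select_workflow(g, ages, wfs, c("beheshti", "cole"), k = 3, seed = 5)
  expect_equal(nrow(rep1$table), 4)
  best <- min(rep1$table$cv_mae)
  sel <- rep1$table$cv_mae[rep1$table$workflow == rep1$best_workflow$name &
                             rep1$table$correction == rep1$best_correction]
  expect_equal(sel, best)
  # identical candidate -> identical MAE at the same seed; order invariance
  rep2 <- select_workflow(g, ages, wfs[c(2, 1)], c("beheshti", "cole"),
                          k = 3, seed = 5)
  expect_equal(sort(rep2$table$cv_mae), sort(rep1$table$cv_mae),
               tolerance = 1e-10)
  # single candidate trivially selected
  rep3 <- select_workflow(g, ages, wfs[1], "beheshti", k = 3, seed = 5)
  expect_equal(rep3$best_correction, "beheshti")
  expect_error(select_workflow(g, ages, list(), k = 3), "empty")
})

test_that("concordance correlation matches hand moments and its bounds", {
  expect_equal(concordance(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(concordance(x, x), 1)
  expect_equal(concordance(x, -x), -1)
  set.seed(8)
  for (r in 1:10) {
    a <- rnorm(20); b <- rnorm(20) + 0.5 * a
    ccc <- concordance(a, b)
    expect_lte(abs(ccc), abs(cor(a, b)) + 1e-12)  # CCC <= |pearson|
  }
  expect_error(concordance(1, 1), "n >= 2")
})

test_that("longitudinal consistency splits pairs at the interval threshold", {
  # 6 subjects, brain age advancing exactly 1 y/y, intervals >= 1.5
  bt <- do.call(rbind, lapply(1:6, function(i) {
    t <- c(0, 1, 2 + 0.5 * i)  # first and last used, middle scan ignored
    data.frame(subject_id = sprintf("s%d", i), scan_time = t,
               chronological_age = 60 + i + t,
               brain_age_raw = 60 + i + t,
               brain_age_corrected = 60 + i + t,
               bag_corrected = 0)
  }))
  class(bt) <- c("bag_table", "data.frame")
  rep <- longitudinal_consistency(bt)
  expect_equal(rep$n_retest, 0)
  expect_true(is.na(rep$ccc_retest))       # absent, not fabricated
  expect_equal(rep$n_consistency, 6)
  expect_equal(rep$pairs$interval, 2 + 0.5 * (1:6))  # (first, last) pairs
  expect_equal(rep$consistency_r, 1, tolerance = 1e-12)
  expect_error(longitudinal_consistency(bt[1:3, ]), ">= 3 subjects")
})

test_that("shuffled brain-age increments decorrelate from elapsed time", {
  set.seed(12)
  n <- 200
  intervals <- runif(n, 1.6, 6)
  dba <- sample(intervals)  # independent of interval by construction
  bt <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = sprintf("s%03d", i), scan_time = c(0, intervals[i]),
               chronological_age = 60, brain_age_raw = 0,
               brain_age_corrected = c(60, 60 + dba[i]), bag_corrected = 0)))
  class(bt) <- c("bag_table", "data.frame")
  rep <- longitudinal_consistency(bt)
  expect_lt(abs(rep$consistency_r), 0.15)
})
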