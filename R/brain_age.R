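#' Gaussian smoothing of a 3D array
#'
#' Separable zero-padded convolution with a truncated (4 sigma) discrete
#' Gaussian, `sigma = FWHM / 2.3548` per axis, expressed in mm and converted
#' to voxels through the grid spacing. The kernel sums to 1, so the total sum
#' is preserved exactly for signals supported away from the edges.
#'
#' @param arr 3D numeric array.
#' @param fwhm full width at half maximum, mm (scalar or per-axis); 0 = no-op.
#' @param spacing mm per voxel per axis.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(arr, fwhm, spacing = c(1, 1, 1)) {
  if (any(fwhm < 0)) stop_bagpd("fwhm must be >= 0")
  fwhm <- rep(fwhm, length.out = 3)
  spacing <- rep(spacing, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    sig <- fwhm[ax] / 2.3548200450309493 / spacing[ax]
    if (sig <= 0) next
    rad <- max(1L, ceiling(4 * sig))
    k <- exp(-0.5 * ((-rad:rad) / sig)^2)
    k <- k / sum(k)
    C <- conv_matrix(d[ax], k, rad)
    arr <- apply_axis(arr, ax, C)
  }
  arr
}

conv_matrix <- function(n, k, rad) {
  C <- matrix(0, n, n)
  for (o in -rad:rad) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    C[cbind(idx[ok], j[ok])] <- C[cbind(idx[ok], j[ok])] + k[o + rad + 1]
  }
  # renormalize edge rows: constants are preserved everywhere, and interior
  # rows are untouched (their kernel mass already sums to 1)
  C / rowSums(C)
}

# multiply matrix M (new x old) along axis `ax` of a 3D array
apply_axis <- function(arr, ax, M) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  dm <- dim(a)
  a <- M %*% matrix(a, dm[1])
  dim(a) <- c(nrow(M), dm[2], dm[3])
  aperm(a, order(perm))
}

# linear-interpolation downsampling matrix: new voxel j sits at the centre of
# the block of `f` old voxels it replaces
resample_matrix <- function(n, f) {
  m <- floor(n / f)
  pos <- (seq_len(m) - 1) * f + (f + 1) / 2
  M <- matrix(0, m, n)
  for (j in seq_len(m)) {
    lo <- floor(pos[j]); w <- pos[j] - lo
    M[j, lo] <- 1 - w
    if (w > 0 && lo + 1 <= n) M[j, lo + 1] <- w
  }
  M
}

#' Smooth and resample a feature grid
#'
#' Gaussian smoothing at the stated FWHM followed by integer-factor
#' downsampling via linear interpolation, mirroring the voxelwise
#' dimensionality-reduction step of typical brain-age feature pipelines.
#'
#' @param grid a `feature_grid`.
#' @param fwhm smoothing FWHM in mm (0 = none).
#' @param factor integer downsampling factor (1 = none).
#' @return a new `feature_grid` on the coarser geometry (mask: any
#'   contributing fine voxel inside the original mask).
#' @export
smooth_and_resample <- function(grid, fwhm = 0, factor = 1L) {
  stopifnot(inherits(grid, "feature_grid"))
  if (fwhm < 0) stop_bagpd("fwhm must be >= 0")
  factor <- as.integer(factor)
  if (factor < 1L) stop_bagpd("resampling factor must be >= 1")
  g <- grid$geometry
  if (fwhm == 0 && factor == 1L) return(grid)
  d <- g$dims
  newd <- if (factor > 1L) pmax(floor(d / factor), 1L) else d
  Ms <- lapply(1:3, function(ax) {
    I <- diag(d[ax])
    if (factor > 1L) resample_matrix(d[ax], factor) else I
  })
  # new mask: downsample the 0/1 mask and keep voxels with any support
  mask_arr <- array(0, d); mask_arr[g$brain_mask] <- 1
  mk <- mask_arr
  for (ax in 1:3) mk <- apply_axis(mk, ax, Ms[[ax]])
  new_mask <- array(mk > 1e-9, dim = newd)

  full <- array(0, d)
  nvi <- which(new_mask)
  out <- matrix(0, nrow(grid$data), length(nvi))
  for (j in seq_len(nrow(grid$data))) {
    full[] <- 0
    full[grid$voxel_index] <- grid$data[j, ]
    sm <- gaussian_smooth(full, fwhm, g$spacing)
    for (ax in 1:3) sm <- apply_axis(sm, ax, Ms[[ax]])
    out[j, ] <- sm[nvi]
  }
  geometry <- grid_geometry(newd, g$spacing * factor, brain_mask = new_mask)
  structure(list(data = out, geometry = geometry, scans = grid$scans,
                 voxel_index = nvi), class = "feature_grid")
}

#' Brain-age estimation workflow description
#'
#' The three named combinations used for model selection are
#' `"S4_R4+GPR"` (4 mm smoothing, 4x resampling, Gaussian-process-style
#' kernel regression), `"S4_R4+PCA+GPR"` (adds a principal-component
#' reduction) and `"S0_R4+LR"` (no smoothing, 4x resampling, lasso).
#'
#' @param smoothing_fwhm mm (0 allowed).
#' @param resample_factor integer >= 1.
#' @param reducer `"none"` or `"principal_components"`.
#' @param regressor `"sparse_linear"` (lasso), `"kernel_gp"` (RBF kernel
#'   ridge, a GP posterior mean) or `"ridge"`.
#' @param name optional label.
#' @return a `workflow` object.
#' @export
workflow <- function(smoothing_fwhm = 0, resample_factor = 1L,
                     reducer = c("none", "principal_components"),
                     regressor = c("sparse_linear", "kernel_gp", "ridge"),
                     name = NULL) {
  reducer <- match.arg(reducer)
  regressor <- match.arg(regressor)
  if (smoothing_fwhm < 0 || resample_factor < 1) stop_bagpd("invalid workflow")
  name <- name %||% sprintf("S%g_R%d+%s%s", smoothing_fwhm, resample_factor,
                            if (reducer == "principal_components") "PCA+" else "",
                            switch(regressor, sparse_linear = "LR",
                                   kernel_gp = "GPR", ridge = "RR"))
  structure(list(smoothing_fwhm = smoothing_fwhm,
                 resample_factor = as.integer(resample_factor),
                 reducer = reducer, regressor = regressor, name = name),
            class = "workflow")
}

#' @rdname workflow
#' @export
default_workflows <- function() list(
  workflow(4, 4L, "none", "kernel_gp", name = "S4_R4+GPR"),
  workflow(4, 4L, "principal_components", "kernel_gp", name = "S4_R4+PCA+GPR"),
  workflow(0, 4L, "none", "sparse_linear", name = "S0_R4+LR"))

# stage count used for documented tie-breaking in select_workflow
workflow_stages <- function(wf) {
  (wf$smoothing_fwhm > 0) + (wf$resample_factor > 1) +
    (wf$reducer != "none") + 1L
}

#' Train a brain-age model
#'
#' Applies the workflow's smoothing/resampling and optional PCA reduction,
#' then fits the regressor of chronological age on voxel features. The lasso
#' penalty is chosen by inner cross-validation; the kernel regressor is an
#' RBF kernel ridge (equivalently a GP posterior mean) with median-heuristic
#' lengthscale.
#'
#' @param features a `feature_grid` of training scans (typically HC).
#' @param ages chronological ages, years, one per scan.
#' @param wf a [workflow()].
#' @param seed integer seed (CV folds, lasso path).
#' @return a `brain_age_model` with a `predict()` method taking a
#'   `feature_grid`.
#' @export
train_brain_age <- function(features, ages, wf = workflow(), seed = 1L) {
  stopifnot(inherits(features, "feature_grid"))
  if (length(ages) != nrow(features$data))
    stop_bagpd("feature/age length mismatch")
  if (sd(ages) < 1e-12) {
    # degenerate constant-age training set: constant predictor
    return(structure(list(wf = wf, constant = ages[1]), class = "brain_age_model"))
  }
  proc <- smooth_and_resample(features, wf$smoothing_fwhm, wf$resample_factor)
  X <- proc$data
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  rot <- NULL
  if (wf$reducer == "principal_components") {
    pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
    ncomp <- max(2L, min(which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= 0.95)))
    ncomp <- min(ncomp, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    Xs <- Xs %*% rot
  }

  model <- with_seed(child_seed(seed, "misc"), {
    switch(wf$regressor,
      sparse_linear = {
        cv <- glmnet::cv.glmnet(Xs, ages, alpha = 1, nfolds = 5)
        list(kind = "glmnet", fit = cv, s = "lambda.min")
      },
      ridge = {
        cv <- glmnet::cv.glmnet(Xs, ages, alpha = 0, nfolds = 5)
        list(kind = "glmnet", fit = cv, s = "lambda.min")
      },
      kernel_gp = {
        D2 <- as.matrix(dist(Xs))^2
        ell2 <- median(D2[upper.tri(D2)])
        ell2 <- if (is.finite(ell2) && ell2 > 0) ell2 else 1
        K <- exp(-D2 / (2 * ell2))
        ybar <- mean(ages)
        alpha <- solve(K + 0.1 * diag(nrow(K)), ages - ybar)
        list(kind = "krr", Xtr = Xs, alpha = alpha, ell2 = ell2, ybar = ybar)
      })
  })
  structure(list(wf = wf, ctr = ctr, scl = scl, rot = rot, model = model,
                 version = "bagpd-model-1"),
            class = "brain_age_model")
}

#' @export
predict.brain_age_model <- function(object, features, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(features$data)))
  proc <- smooth_and_resample(features, object$wf$smoothing_fwhm,
                              object$wf$resample_factor)
  X <- sweep(sweep(proc$data, 2, object$ctr), 2, object$scl, "/")
  if (!is.null(object$rot)) X <- X %*% object$rot
  m <- object$model
  if (m$kind == "glmnet") {
    as.numeric(predict(m$fit, newx = X, s = m$s))
  } else {
    D2 <- outer(rowSums(X^2), rowSums(m$Xtr^2), `+`) - 2 * X %*% t(m$Xtr)
    K <- exp(-pmax(D2, 0) / (2 * m$ell2))
    as.numeric(m$ybar + K %*% m$alpha)
  }
}

#' Fit an age-bias correction on healthy controls
#'
#' Brain age is typically over-estimated in young and under-estimated in old
#' subjects. Two linear recalibrations are supported:
#' * `cole`: OLS of predicted age on chronological age,
#'   `pred = a + b * chron`; corrected prediction `(pred - a) / b`.
#' * `beheshti`: OLS of the gap on chronological age,
#'   `BAG = a + b * chron`; corrected gap `BAG - (a + b * chron)`.
#'
#' @param pred predicted brain ages (HC), years.
#' @param chron chronological ages (HC), years.
#' @param method `"beheshti"` (default) or `"cole"`.
#' @return a `bias_correction` with `intercept`, `slope`, `method`,
#'   `training_n`.
#' @export
fit_bias_correction <- function(pred, chron, method = c("beheshti", "cole")) {
  method <- match.arg(method)
  if (length(pred) != length(chron)) stop_bagpd("length mismatch")
  if (length(pred) < 10) stop_bagpd("need >= 10 HC pairs to fit a bias correction")
  if (var(chron) <= 0) stop_bagpd("chronological age has zero variance")
  y <- if (method == "cole") pred else pred - chron
  b <- cov(y, chron) / var(chron)
  a <- mean(y) - b * mean(chron)
  if (method == "cole" && abs(b) < 1e-8)
    stop_bagpd("cole correction undefined: fitted slope ~ 0")
  structure(list(method = method, intercept = a, slope = b,
                 training_n = length(pred)), class = "bias_correction")
}

# corrected BAG for raw predictions under a fitted correction
correct_bag <- function(correction, pred, chron) {
  if (correction$method == "cole") {
    (pred - correction$intercept) / correction$slope - chron
  } else {
    (pred - chron) - (correction$intercept + correction$slope * chron)
  }
}

#' Apply a brain-age model + bias correction to scans
#'
#' @param model a `brain_age_model`.
#' @param correction a `bias_correction` (fitted on HC).
#' @param features a `feature_grid` of scans to score.
#' @param chron chronological ages at scan, years (default taken from
#'   `features$scans$age`).
#' @return a `bag_table` data.frame: `subject_id`, `scan_time`,
#'   `chronological_age`, `brain_age_raw`, `brain_age_corrected`,
#'   `bag_corrected`.
#' @export
apply_bag <- function(model, correction, features, chron = NULL) {
  chron <- chron %||% features$scans$age
  if (length(chron) != nrow(features$data))
    stop_bagpd("feature/age length mismatch")
  raw <- predict(model, features)
  bag <- correct_bag(correction, raw, chron)
  out <- data.frame(subject_id = features$scans$subject_id,
                    scan_time = features$scans$scan_time,
                    chronological_age = chron,
                    brain_age_raw = raw,
                    brain_age_corrected = chron + bag,
                    bag_corrected = bag,
                    stringsAsFactors = FALSE)
  class(out) <- c("bag_table", "data.frame")
  out
}

#' Cross-validated workflow / bias-correction selection
#'
#' Evaluates each (workflow, correction-method) pair by k-fold
#' cross-validation on HC: the model and the bias correction are fitted on
#' the training folds and the mean absolute error of corrected brain age is
#' measured on the held-out fold. The pair with the lowest CV MAE wins; ties
#' are broken in favour of the workflow with fewer pipeline stages.
#' Folds are stratified by age quantile by default.
#'
#' @param hc_features HC `feature_grid` (one scan per subject recommended).
#' @param hc_ages chronological ages.
#' @param workflows list of [workflow()]s.
#' @param corrections character vector of correction methods.
#' @param k folds (>= 2).
#' @param seed integer seed.
#' @param stratify_by_age stratify folds by age quantile.
#' @return a `selection_report`: `$table` (workflow, correction, cv_mae),
#'   `$best_workflow`, `$best_correction`.
#' @export
select_workflow <- function(hc_features, hc_ages, workflows = default_workflows(),
                            corrections = c("beheshti", "cole"), k = 5L,
                            seed = 1L, stratify_by_age = TRUE) {
  if (length(workflows) == 0) stop_bagpd("empty workflow list")
  if (k < 2) stop_bagpd("k must be >= 2")
  n <- nrow(hc_features$data)
  folds <- with_seed(child_seed(seed, "misc"), {
    if (stratify_by_age) {
      strata <- cut(rank(hc_ages, ties.method = "first"),
                    breaks = k, labels = FALSE)
      f <- integer(n)
      for (s in unique(strata)) {
        id <- which(strata == s)
        f[id] <- sample(rep_len(seq_len(k), length(id)))
      }
      f
    } else sample(rep_len(seq_len(k), n))
  })
  rows <- list()
  for (wi in seq_along(workflows)) {
    wf <- workflows[[wi]]
    # predictions from fold-wise retrained models, shared across corrections
    pred <- rep(NA_real_, n)
    for (fold in seq_len(k)) {
      tr <- folds != fold
      sub_tr <- subset_grid(hc_features, tr)
      m <- train_brain_age(sub_tr, hc_ages[tr], wf, seed = seed + fold)
      pred[!tr] <- predict(m, subset_grid(hc_features, !tr))
    }
    for (corr in corrections) {
      cb <- rep(NA_real_, n)
      for (fold in seq_len(k)) {
        tr <- folds != fold
        bc <- fit_bias_correction(pred[tr], hc_ages[tr], corr)
        cb[!tr] <- correct_bag(bc, pred[!tr], hc_ages[!tr])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        workflow = wf$name, correction = corr, cv_mae = mean(abs(cb)),
        stages = workflow_stages(wf), wf_index = wi, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$cv_mae, tab$stages)
  best <- tab[ord[1], ]
  structure(list(table = tab[, c("workflow", "correction", "cv_mae")],
                 best_workflow = workflows[[best$wf_index]],
                 best_correction = best$correction,
                 folds = folds),
            class = "selection_report")
}

#' Subset a feature grid by scan
#'
#' @param grid a `feature_grid`.
#' @param keep logical or integer scan index.
#' @return a `feature_grid` with the selected scans.
#' @export
subset_grid <- function(grid, keep) {
  structure(list(data = grid$data[keep, , drop = FALSE],
                 geometry = grid$geometry,
                 scans = grid$scans[keep, , drop = FALSE],
                 voxel_index = grid$voxel_index), class = "feature_grid")
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Penalizes both dispersion and location shifts,
#' so CCC <= |Pearson r|.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return scalar in \[-1, 1\].
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop_bagpd("need n >= 2 paired values")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den <= 0) stop_bagpd("CCC undefined: zero denominator")
  2 * cxy / den
}

#' Retest reliability and longitudinal consistency of BAG
#'
#' Subjects with >= 2 scans are split by the interval between their first and
#' last scan: intervals shorter than `threshold` form the retest set (BAG is
#' expected stable; reported as CCC between first- and last-scan BAG), and
#' intervals of at least `threshold` form the consistency set (brain age is
#' expected to advance with time; reported as the Pearson correlation between
#' the increase in brain age and the elapsed time, with its p-value).
#'
#' @param bag_table a `bag_table`.
#' @param threshold years; scans `>= threshold` apart go to the consistency
#'   set (half-open split).
#' @return a `consistency_report` with `ccc_retest` (or `NA` if no qualifying
#'   pairs), `consistency_r`, `consistency_p`, counts, and the per-subject
#'   pair table.
#' @export
longitudinal_consistency <- function(bag_table, threshold = 1.5) {
  sp <- split(bag_table, bag_table$subject_id)
  sp <- Filter(function(d) nrow(d) >= 2, sp)
  if (length(sp) < 3) stop_bagpd("need >= 3 subjects with >= 2 scans")
  pairs <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$scan_time), ]
    f <- d[1, ]; l <- d[nrow(d), ]            # first and last scan only
    data.frame(subject_id = f$subject_id,
               interval = l$scan_time - f$scan_time,
               d_brain_age = l$brain_age_corrected - f$brain_age_corrected,
               bag_first = f$bag_corrected, bag_last = l$bag_corrected,
               stringsAsFactors = FALSE)
  }))
  retest <- pairs[pairs$interval < threshold, ]
  consist <- pairs[pairs$interval >= threshold, ]
  ccc <- if (nrow(retest) >= 2) concordance(retest$bag_first, retest$bag_last) else NA_real_
  if (nrow(consist) >= 3) {
    ct <- cor.test(consist$d_brain_age, consist$interval)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  structure(list(ccc_retest = ccc, n_retest = nrow(retest),
                 consistency_r = r, consistency_p = p,
                 n_consistency = nrow(consist), pairs = pairs,
                 threshold = threshold),
            class = "consistency_report")
}

#' @importFrom stats cor.test prcomp
NULL
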