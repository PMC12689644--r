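#' Per-parcel mean features
#'
#' Mean feature value over the member voxels of each atlas parcel, per scan
#' (the parcelwise analogue of mean gray-matter volume per region).
#'
#' @param grid a `feature_grid`.
#' @param atlas a `parcel_atlas` aligned to the grid.
#' @return scans x parcels matrix with parcel names as columns.
#' @export
parcel_means <- function(grid, atlas) {
  stopifnot(inherits(grid, "feature_grid"), inherits(atlas, "parcel_atlas"))
  if (!all(dim(atlas$labels) == grid$geometry$dims))
    stop_bagpd("atlas not aligned to grid")
  lab <- atlas$labels[grid$voxel_index]
  out <- matrix(NA_real_, nrow(grid$data), length(atlas$ids),
                dimnames = list(NULL, atlas$names))
  for (j in seq_along(atlas$ids)) {
    sel <- lab == atlas$ids[j]
    if (!any(sel)) stop_bagpd("parcel '%s' has no voxels inside the grid mask",
                              atlas$names[j])
    out[, j] <- rowMeans(grid$data[, sel, drop = FALSE])
  }
  out
}

#' Mass-univariate group GLM over features
#'
#' For every feature (voxel or parcel), fits the linear model
#' `feature ~ subtype + covariates` by OLS and reports the t statistic and
#' two-sided p-value for the subtype coefficient, with Benjamini-Hochberg
#' adjusted p-values and significance flags. The design matrix is shared
#' across features, so the fit is a single multi-response least squares.
#'
#' Sign convention: subtype is coded 0/1 in the order given by `levels`
#' (default alphabetical), so positive t means higher feature values — i.e.
#' less atrophy — in the second level.
#'
#' @param values subjects x features numeric matrix (single feature vectors
#'   allowed).
#' @param subtype factor/character with exactly 2 levels.
#' @param covars data.frame of covariates (e.g. age, sex, total intracranial
#'   volume, latent disease time), or `NULL`.
#' @param levels optional explicit level order.
#' @param alpha significance level for the flags.
#' @return a `stat_map` data.frame: feature, t_value, p_raw, p_adjusted,
#'   significant_raw, significant_adjusted. Rank-deficient designs are an
#'   error; individual features with zero residual variance get `NA` flags.
#' @export
groupwise_glm <- function(values, subtype, covars = NULL, levels = NULL,
                          alpha = 0.05) {
  values <- as.matrix(values)
  subtype <- as.character(subtype)
  lv <- levels %||% sort(unique(subtype))
  if (length(lv) != 2) stop_bagpd("subtype must have exactly 2 levels")
  if (min(table(subtype)) < 3) stop_bagpd("each group needs n >= 3")
  g <- as.numeric(subtype == lv[2])
  X <- cbind(intercept = 1, subtype = g)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    for (nm in names(covars)) {
      v <- covars[[nm]]
      X <- cbind(X, if (is.numeric(v)) v else as.numeric(factor(v)) - 1)
      colnames(X)[ncol(X)] <- nm
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_bagpd("design matrix is rank deficient (collinear covariates?)")
  n <- nrow(X); ppar <- ncol(X); df <- n - ppar
  if (df < 1) stop_bagpd("not enough subjects for the design")
  coefs <- qr.coef(qrX, values)
  res <- values - X %*% coefs
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- coefs[2, ] / se
  tval[se == 0] <- NA_real_
  p <- 2 * pt(-abs(tval), df)
  padj <- bh_adjust(ifelse(is.na(p), 1, p))
  padj[is.na(p)] <- NA_real_
  out <- data.frame(feature = colnames(values) %||% seq_len(ncol(values)),
                    t_value = unname(tval), p_raw = unname(p),
                    p_adjusted = unname(padj),
                    significant_raw = unname(p < alpha),
                    significant_adjusted = unname(padj < alpha),
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_map", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `p_adj(i) = min_{j >= i} p_(j) * m / j`, capped at 1, in the original
#' order of the input.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_bagpd("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Voxelwise subtype comparison pipeline
#'
#' Restricts to baseline scans of subjects with a known subtype, optionally
#' smooths/resamples, and runs [groupwise_glm()] per masked voxel with age,
#' sex, total intracranial volume (mask-summed template volume) and latent
#' disease time as covariates.
#'
#' @param grid a `feature_grid`.
#' @param cohort the matching `long_cohort`.
#' @param latent optional latent-time table from [latent_times()] (baseline
#'   latent disease time covariate); omitted if `NULL`.
#' @param fwhm,factor optional smoothing / resampling before testing.
#' @param alpha significance level.
#' @return a `stat_map` over masked voxels, with attribute `voxel_index`.
#' @export
voxelwise_comparison <- function(grid, cohort, latent = NULL, fwhm = 0,
                                 factor = 1L, alpha = 0.05) {
  g <- if (fwhm > 0 || factor > 1) smooth_and_resample(grid, fwhm, factor) else grid
  sc <- g$scans
  base <- !duplicated(sc$subject_id)
  s <- cohort$subjects[match(sc$subject_id, cohort$subjects$subject_id), ]
  keep <- base & s$group == "PD" & s$subtype %in% c("fast", "slow")
  vals <- g$data[keep, , drop = FALSE]
  tiv <- rowSums(vals)  # mask-summed volume as intracranial-volume analogue
  covars <- data.frame(age = sc$age[keep], sex = s$sex[keep], tiv = tiv)
  if (!is.null(latent)) {
    lt <- latent[!duplicated(latent$subject_id), ]
    covars$latent_time <- lt$latent_time[match(sc$subject_id[keep], lt$subject_id)]
  }
  sm <- groupwise_glm(vals, s$subtype[keep], covars, levels = c("fast", "slow"),
                      alpha = alpha)
  attr(sm, "voxel_index") <- g$voxel_index
  sm
}
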