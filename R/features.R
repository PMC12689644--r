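#' Voxel grid geometry
#'
#' @param dims integer voxel counts per axis (length 3, each >= 4).
#' @param spacing mm per voxel per axis.
#' @param brain_mask logical array of `dims`, or `NULL` for the default
#'   spherical mask (radius 0.45 of the smallest half-extent).
#' @return a `grid_geometry` object with `dims`, `spacing`, `brain_mask`.
#' @export
grid_geometry <- function(dims = c(16L, 16L, 16L), spacing = c(8, 8, 8),
                          brain_mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop_bagpd("grid dimensions must be length 3 and >= 4 per axis")
  if (any(spacing <= 0)) stop_bagpd("spacing must be > 0")
  if (is.null(brain_mask)) {
    r <- voxel_radius(dims)
    brain_mask <- array(r <= 0.9, dim = dims)
  }
  stopifnot(all(dim(brain_mask) == dims))
  if (!any(brain_mask)) stop_bagpd("brain mask is empty")
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 brain_mask = brain_mask), class = "grid_geometry")
}

# normalized radius from grid centre, in units of the smallest half-extent
voxel_radius <- function(dims) {
  ax <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) / ((min(dims) - 1) / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  sqrt(r2)
}

#' Shell/core parcel atlas for a grid
#'
#' An analytic stand-in for a cortical/subcortical parcellation: the masked
#' sphere is split into a "cortical shell" (outer rim) and "subcortical core"
#' (centre), each subdivided into octants, yielding 16 parcels.
#'
#' @param geometry a [grid_geometry()].
#' @param shell_radius normalized radius separating core from shell.
#' @return a `parcel_atlas`: integer `labels` array (0 = background) and
#'   `names` per parcel; `$tissue` marks each parcel `"shell"` or `"core"`.
#' @export
shell_core_atlas <- function(geometry, shell_radius = 0.6) {
  d <- geometry$dims
  r <- voxel_radius(d)
  shell <- geometry$brain_mask & r > shell_radius
  core <- geometry$brain_mask & r <= shell_radius
  oct <- octant_index(d)
  labels <- array(0L, dim = d)
  labels[core] <- oct[core]
  labels[shell] <- oct[shell] + 8L
  nm <- c(paste0("core_oct", 1:8), paste0("shell_oct", 1:8))
  keep <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, names = nm[keep], ids = keep,
                 tissue = ifelse(keep > 8L, "shell", "core")),
            class = "parcel_atlas")
}

octant_index <- function(dims) {
  ax <- lapply(dims, function(d) as.integer(seq_len(d) > d / 2))
  o <- outer(outer(ax[[1]], 2L * ax[[2]], `+`), 4L * ax[[3]], `+`)
  array(o + 1L, dim = dims)
}

# Deterministic smooth random field on the grid: white noise convolved with a
# Gaussian kernel, rescaled to unit sd over the mask.
smooth_field <- function(dims, fwhm_vox, mask = NULL) {
  noise <- array(rnorm(prod(dims)), dim = dims)
  f <- gaussian_smooth(noise, fwhm = rep(fwhm_vox, 3), spacing = c(1, 1, 1))
  s <- if (is.null(mask)) sd(f) else sd(f[mask])
  f / max(s, 1e-12)
}

# Spatial maps (template, age slope a(v), subtype slopes b(v)) depend only on
# the geometry, via a fixed internal seed: models trained on one simulated
# cohort remain applicable to another on the same grid.
feature_maps <- function(geometry) {
  d <- geometry$dims
  with_seed(20260901L, {
    r <- voxel_radius(d)
    mask <- geometry$brain_mask
    template <- array(0, dim = d)
    template[mask] <- 600 + 80 * smooth_field(d, 4, mask)[mask]
    # age-atrophy rate, units/year, strictly positive so noise-free features
    # are monotone nonincreasing in age
    a <- array(0, dim = d)
    a[mask] <- pmax(1.5 + 0.5 * smooth_field(d, 4, mask)[mask], 0.2)
    # subtype-specific *excess* atrophy on top of accelerated normal aging:
    # fast-progressing disease hits the cortical shell harder,
    # slow-progressing the subcortical core
    shell <- mask & r > 0.6
    core <- mask & r <= 0.6
    b_shell <- array(0, dim = d); b_shell[shell] <- 1.0; b_shell[core] <- 0.2
    b_core <- array(0, dim = d); b_core[shell] <- 0.2; b_core[core] <- 1.0
    list(template = template, a = a, b_shell = b_shell, b_core = b_core)
  })
}

#' Simulate gray-matter feature grids for a cohort's MRI scans
#'
#' Stands in for preprocessed, spatially normalized gray-matter volume maps.
#' Per scan, the voxel value is
#' `template(v) - a(v) * (age - 40 + u_i + d_i(t)) - b_sub(v) * excess_w * d_i(t) + noise`:
#' `u_i` is a per-subject brain-aging offset (the ground-truth BAG of a
#' healthy brain); `d_i(t) = accel * max(0, t_dx + delta_i)` is latent
#' disease time scaled by a subtype-dependent acceleration, which *ages the
#' brain along the normal atrophy pattern* (so a brain-age model reads it
#' out as an increased BAG of about `d_i` years) and additionally removes
#' subtype-specific excess volume (fast subtypes in the cortical shell, slow
#' subtypes in the subcortical core — the signal the morphometry module
#' looks for). With `noise_sd = 0` every voxel is monotone nonincreasing in
#' age.
#'
#' A subset of subjects receives follow-up scans (default schedule emulates a
#' cohort where most subjects have baseline-only MRI).
#'
#' @param cohort,truth output of [simulate_cohort()].
#' @param geometry a [grid_geometry()].
#' @param seed integer seed (noise and scan schedule only; spatial maps are a
#'   fixed function of the geometry).
#' @param noise_sd sd of the spatially smooth scan noise, template units.
#' @param u_sd sd of the per-subject brain-aging offset, years.
#' @param accel named acceleration per subtype (years of excess brain aging
#'   per year of latent disease time).
#' @param excess_w weight of the subtype-specific excess-atrophy pattern
#'   relative to the accelerated-aging component.
#' @param p_longitudinal fraction of subjects receiving follow-up scans.
#' @return a `feature_grid`: `$data` (scans x voxels matrix, masked voxels
#'   only), `$geometry`, `$scans` (subject_id, scan_time, age, and the
#'   ground-truth columns `true_u`, `true_disease_time`), `$voxel_index`.
#' @export
simulate_features <- function(cohort, truth, geometry = grid_geometry(),
                              seed = 1L, noise_sd = 16, u_sd = 5,
                              accel = c(fast = 2.0, slow = 0.6, unknown = 1.0),
                              excess_w = 0.5, p_longitudinal = 0.4) {
  stopifnot(inherits(cohort, "long_cohort"), inherits(geometry, "grid_geometry"))
  maps <- feature_maps(geometry)
  set.seed(child_seed(seed, "features"))

  s <- cohort$subjects
  n <- nrow(s)
  u <- rnorm(n, 0, u_sd)

  # scan schedule: everyone a baseline scan; of the longitudinal fraction,
  # some get a short-interval retest rescan (reliability protocol), the rest
  # 1-3 follow-ups over several years
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- 0
    times <- t0
    if (runif(1) < p_longitudinal) {
      if (runif(1) < 0.3) {
        times <- c(t0, t0 + runif(1, 0.25, 1.2))
      } else {
        extra <- sample(1:3, 1)
        times <- c(t0, t0 + sort(runif(extra, 1.6, 6)))
      }
    }
    scans[[i]] <- data.frame(subject_id = s$subject_id[i],
                             scan_time = times, stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, scans)
  i_of <- match(scans$subject_id, s$subject_id)
  scans$age <- s$age_at_baseline[i_of] + scans$scan_time
  is_pd <- s$group[i_of] == "PD"
  delta <- ifelse(is.na(s$true_time_shift[i_of]), 0, s$true_time_shift[i_of])
  acc <- ifelse(is_pd, accel[ifelse(is.na(s$subtype[i_of]), "unknown", s$subtype[i_of])], 0)
  tsd <- s$entry_time[i_of] + scans$scan_time        # time since diagnosis at scan
  d_t <- acc * pmax(0, tsd + delta)
  d_t[!is_pd] <- 0
  scans$true_u <- u[i_of]
  scans$true_disease_time <- d_t
  shell_w <- ifelse(is_pd & !is.na(s$subtype[i_of]) & s$subtype[i_of] == "slow", 0, 1)

  mask <- geometry$brain_mask
  vi <- which(mask)
  tmpl <- maps$template[vi]; av <- maps$a[vi]
  bsh <- maps$b_shell[vi]; bco <- maps$b_core[vi]
  m <- nrow(scans)
  X <- matrix(0, m, length(vi))
  d3 <- geometry$dims
  for (j in seq_len(m)) {
    bmap <- if (shell_w[j] == 1) bsh else bco
    base <- tmpl - av * (scans$age[j] - 40 + scans$true_u[j] + d_t[j]) -
      excess_w * bmap * d_t[j]
    eta <- if (noise_sd > 0) noise_sd * smooth_field(d3, 2, mask)[vi] else 0
    X[j, ] <- base + eta
  }
  structure(list(data = X, geometry = geometry, scans = scans,
                 voxel_index = vi), class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("feature_grid: %d scans x %d masked voxels (grid %s)\n",
              nrow(x$data), ncol(x$data), paste(x$geometry$dims, collapse = "x")))
  invisible(x)
}

#' Write / read feature grids (binary array + text sidecar)
#'
#' The scans-by-voxels matrix is stored as little-endian float64 with a JSON
#' sidecar describing geometry and scan metadata.
#'
#' @param grid a `feature_grid`.
#' @param stem path stem.
#' @export
write_features <- function(grid, stem) {
  con <- file(paste0(stem, "_features.bin"), "wb")
  writeBin(as.vector(grid$data), con, size = 8, endian = "little")
  close(con)
  side <- list(dims = grid$geometry$dims, spacing = grid$geometry$spacing,
               n_scans = nrow(grid$data), n_voxels = ncol(grid$data),
               voxel_index = grid$voxel_index)
  jsonlite::write_json(side, paste0(stem, "_features.json"), auto_unbox = FALSE)
  data.table::fwrite(grid$scans, paste0(stem, "_scans.tsv"), sep = "\t")
  invisible(stem)
}

#' @rdname write_features
#' @export
read_features <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, "_features.json"), simplifyVector = TRUE)
  con <- file(paste0(stem, "_features.bin"), "rb")
  v <- readBin(con, "double", n = side$n_scans * side$n_voxels, size = 8,
               endian = "little")
  close(con)
  dims <- as.integer(side$dims)
  mask <- array(FALSE, dims); mask[side$voxel_index] <- TRUE
  geometry <- grid_geometry(dims, side$spacing, brain_mask = mask)
  scans <- as.data.frame(data.table::fread(paste0(stem, "_scans.tsv")))
  structure(list(data = matrix(v, side$n_scans, side$n_voxels),
                 geometry = geometry, scans = scans,
                 voxel_index = as.integer(side$voxel_index)),
            class = "feature_grid")
}
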