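#' Min-max normalize outcomes to their theoretical ranges
#'
#' Maps each observed value to `(v - min) / (max - min)`; outcomes whose
#' higher values indicate *better* function (e.g. a cognitive screen) are
#' additionally inverted (`v -> 1 - v`) so that, after harmonization, larger
#' values always mean worse disease and all progression slopes are positive.
#' The mapping metadata is retained so values can be round-tripped.
#'
#' @param cohort a `long_cohort`.
#' @param specs named list of [outcome_spec()]s covering every observed
#'   outcome (default: the cohort's own).
#' @param out_of_range `"error"` or `"clamp"` for values outside the
#'   theoretical range.
#' @return the cohort with a `value_norm` column on `$observations` and a
#'   `normalization` attribute.
#' @export
normalize_outcomes <- function(cohort, specs = cohort$outcomes,
                               out_of_range = c("error", "clamp")) {
  out_of_range <- match.arg(out_of_range)
  obs <- cohort$observations
  missing_specs <- setdiff(unique(obs$outcome), names(specs))
  if (length(missing_specs))
    stop_bagpd("no outcome_spec for: %s", paste(missing_specs, collapse = ", "))
  idx <- match(obs$outcome, names(specs))
  lo <- vapply(specs, `[[`, 0, "theoretical_min")[idx]
  hi <- vapply(specs, `[[`, 0, "theoretical_max")[idx]
  dirs <- vapply(specs, `[[`, "", "direction")[idx]
  bad <- obs$value < lo | obs$value > hi
  if (any(bad)) {
    if (out_of_range == "error")
      stop_bagpd("%d values outside their theoretical range (set out_of_range='clamp')",
                 sum(bad))
    obs$value <- clamp(obs$value, lo, hi)
  }
  v <- (obs$value - lo) / (hi - lo)
  obs$value_norm <- ifelse(dirs == "higher_better", 1 - v, v)
  cohort$observations <- obs
  attr(cohort, "normalization") <- list(specs = specs)
  cohort
}

#' Undo outcome normalization
#'
#' @param values normalized values.
#' @param outcome outcome names (recycled).
#' @param specs outcome specs.
#' @return raw-scale values.
#' @export
denormalize_outcomes <- function(values, outcome, specs) {
  idx <- match(outcome, names(specs))
  lo <- vapply(specs, `[[`, 0, "theoretical_min")[idx]
  hi <- vapply(specs, `[[`, 0, "theoretical_max")[idx]
  dirs <- vapply(specs, `[[`, "", "direction")[idx]
  v <- ifelse(dirs == "higher_better", 1 - values, values)
  unname(lo + v * (hi - lo))
}

#' LTJMM fitting specification
#'
#' @param outcomes outcome names to include (default: all in the cohort).
#' @param covariates subject covariates entering `x_i` (default age at
#'   diagnosis, centred and scaled to decades, and sex).
#' @param chains number of MCMC chains (>= 2).
#' @param iterations total iterations per chain.
#' @param warmup warm-up (discarded) iterations per chain (< iterations).
#' @param rhat_threshold convergence threshold on split-R-hat (> 1).
#' @return an `ltjmm_spec`.
#' @export
ltjmm_spec <- function(outcomes = NULL,
                       covariates = c("age_at_diagnosis", "sex"),
                       chains = 4L, iterations = 4000L, warmup = 2000L,
                       rhat_threshold = 1.05) {
  if (chains < 2) stop_bagpd("chains must be >= 2")
  if (!(warmup < iterations)) stop_bagpd("warmup must be < iterations")
  if (!(rhat_threshold > 1)) stop_bagpd("rhat_threshold must be > 1")
  structure(list(outcomes = outcomes, covariates = covariates,
                 chains = as.integer(chains), iterations = as.integer(iterations),
                 warmup = as.integer(warmup), rhat_threshold = rhat_threshold),
            class = "ltjmm_spec")
}

# assemble PD observations into flat vectors + per-subject design matrix
ltjmm_data <- function(cohort, spec) {
  subj <- cohort$subjects[cohort$subjects$group == "PD", ]
  obs <- cohort$observations
  obs <- obs[obs$subject_id %in% subj$subject_id, ]
  if (is.null(obs$value_norm))
    stop_bagpd("cohort not normalized; call normalize_outcomes() first")
  kn <- spec$outcomes %||% sort(unique(obs$outcome))
  obs <- obs[obs$outcome %in% kn, ]
  if (length(kn) < 2) stop_bagpd("LTJMM requires >= 2 outcomes")
  subj <- subj[subj$subject_id %in% obs$subject_id, ]

  X <- matrix(1, nrow(subj), 1, dimnames = list(subj$subject_id, "intercept"))
  for (cv in spec$covariates) {
    x <- switch(cv,
      age_at_diagnosis = (subj$age_at_diagnosis - 60) / 10,
      sex = as.numeric(subj$sex == "M"),
      {
        if (!cv %in% names(subj)) stop_bagpd("unknown covariate '%s'", cv)
        v <- subj[[cv]]
        if (is.numeric(v)) scale(v)[, 1] else as.numeric(factor(v)) - 1
      })
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- cv
  }
  list(y = obs$value_norm,
       i = match(obs$subject_id, subj$subject_id),
       k = match(obs$outcome, kn),
       t = obs$time,
       X = X, subjects = subj$subject_id, outcomes = kn,
       n = nrow(subj), K = length(kn), p = ncol(X))
}

# One Gibbs chain for the latent-time joint mixed-effects model. The model
# is linear-Gaussian given the bilinear gamma*delta term, so every full
# conditional is conjugate (normal or inverse-gamma) and plain Gibbs mixes
# well at this scale.
ltjmm_gibbs <- function(dat, iterations, warmup, seed,
                        priors = ltjmm_priors()) {
  set.seed(seed)
  n <- dat$n; K <- dat$K; p <- dat$p
  y <- dat$y; ii <- dat$i; kk <- dat$k; t <- dat$t; X <- dat$X
  N <- length(y)
  cell <- (kk - 1L) * n + ii
  cells <- sort(unique(cell))
  cell_pos <- match(cell, cells)
  cell_i <- ((cells - 1L) %% n) + 1L
  cell_k <- ((cells - 1L) %/% n) + 1L
  nc <- length(cells)

  obs_k <- split(seq_len(N), kk)
  Xobs <- X[ii, , drop = FALSE]
  XtX_k <- lapply(obs_k, function(id) crossprod(Xobs[id, , drop = FALSE]))

  # state
  beta <- matrix(0, K, p); gamma <- rep(0.05, K)
  delta <- rep(0, n); a0 <- rep(0, nc); a1 <- rep(0, nc)
  s2_eps <- rep(0.01, K); s2_d <- 1; s2_a0 <- rep(0.01, K); s2_a1 <- rep(1e-4, K)

  n_save <- iterations - warmup
  draws <- list(beta = array(NA_real_, c(n_save, K, p)),
                gamma = matrix(NA_real_, n_save, K),
                delta = matrix(NA_real_, n_save, n),
                s2_eps = matrix(NA_real_, n_save, K),
                s2_d = numeric(n_save))
  a0_sum <- rep(0, nc); a1_sum <- rep(0, nc)

  tb <- priors$beta_sd^2; tg <- priors$gamma_sd^2
  n_cell_obs <- as.vector(rowsum(rep(1, N), cell_pos))
  sum_t2_cell <- as.vector(rowsum(t^2, cell_pos))

  for (it in seq_len(iterations)) {
    xb <- rowSums(Xobs * beta[kk, , drop = FALSE])
    g_o <- gamma[kk]
    a0_o <- a0[cell_pos]; a1_o <- a1[cell_pos]
    se2 <- s2_eps[kk]

    # beta_k
    r <- y - g_o * (t + delta[ii]) - a0_o - a1_o * t
    for (k in seq_len(K)) {
      id <- obs_k[[k]]
      A <- XtX_k[[k]] / s2_eps[k] + diag(1 / tb, p)
      b <- crossprod(Xobs[id, , drop = FALSE], r[id]) / s2_eps[k]
      ch <- chol(A)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      beta[k, ] <- mu + backsolve(ch, rnorm(p))
    }
    xb <- rowSums(Xobs * beta[kk, , drop = FALSE])

    # gamma_k (slope on latent time t + delta)
    s <- t + delta[ii]
    r <- y - xb - a0_o - a1_o * t
    for (k in seq_len(K)) {
      id <- obs_k[[k]]
      prec <- sum(s[id]^2) / s2_eps[k] + 1 / tg
      mu <- sum(s[id] * r[id]) / s2_eps[k] / prec
      gamma[k] <- rnorm(1, mu, sqrt(1 / prec))
    }
    g_o <- gamma[kk]

    # delta_i (shared time shift)
    r <- y - xb - g_o * t - a0_o - a1_o * t
    w <- g_o / se2
    prec_d <- as.vector(rowsum(g_o * w, ii, reorder = TRUE)) + 1 / s2_d
    mean_d <- as.vector(rowsum(w * r, ii, reorder = TRUE)) / prec_d
    delta <- rnorm(n, mean_d, sqrt(1 / prec_d))

    # location sweep: the likelihood is invariant under
    # (delta + c, beta0_k - gamma_k c); Gibbs-sample the shift c from its
    # conditional under the priors so the soft mean-zero anchoring of delta
    # mixes in one step instead of a slow random walk
    prec_c <- n / s2_d + sum(gamma^2) / tb
    mean_c <- (sum(delta) / s2_d - sum(gamma * beta[, 1]) / tb) / prec_c
    cshift <- rnorm(1, mean_c, sqrt(1 / prec_c))
    delta <- delta - cshift
    beta[, 1] <- beta[, 1] + gamma * cshift
    xb <- rowSums(Xobs * beta[kk, , drop = FALSE])

    # a0_ik (random intercepts)
    r <- y - xb - g_o * (t + delta[ii]) - a1_o * t
    prec0 <- n_cell_obs / s2_eps[cell_k] + 1 / s2_a0[cell_k]
    m0 <- as.vector(rowsum(r / se2, cell_pos)) / prec0
    a0 <- rnorm(nc, m0, sqrt(1 / prec0))
    a0_o <- a0[cell_pos]

    # per-subject sweep: gamma_k delta_i and alpha0_ik are likelihood-
    # equivalent subject-outcome constants, so delta_i is identified only
    # through the priors; Gibbs-sample the trade-off
    # (delta_i + e_i, alpha0_ik - gamma_k e_i) directly
    gk_cell <- gamma[cell_k]
    s20_cell <- s2_a0[cell_k]
    prec_e <- 1 / s2_d + as.vector(rowsum(gk_cell^2 / s20_cell, cell_i))
    mean_e <- (-delta / s2_d +
                 as.vector(rowsum(gk_cell * a0 / s20_cell, cell_i))) / prec_e
    e <- rnorm(n, mean_e, sqrt(1 / prec_e))
    delta <- delta + e
    a0 <- a0 - gk_cell * e[cell_i]
    a0_o <- a0[cell_pos]

    # a1_ik (random slopes)
    r <- y - xb - g_o * (t + delta[ii]) - a0_o
    prec1 <- sum_t2_cell / s2_eps[cell_k] + 1 / s2_a1[cell_k]
    m1 <- as.vector(rowsum(t * r / se2, cell_pos)) / prec1
    a1 <- rnorm(nc, m1, sqrt(1 / prec1))
    a1_o <- a1[cell_pos]

    # per-outcome sweep: gamma_k trades against the mean random slope (and,
    # through gamma_k delta_i, the random intercepts); the transformation
    # (gamma_k + e, a1_ik - e, a0_ik - e delta_i) is likelihood-invariant,
    # so sample e from its conditional under the priors
    for (k in seq_len(K)) {
      idc <- which(cell_k == k)
      di <- delta[cell_i[idc]]
      prec_g <- 1 / tg + length(idc) / s2_a1[k] + sum(di^2) / s2_a0[k]
      mean_g <- (-gamma[k] / tg + sum(a1[idc]) / s2_a1[k] +
                   sum(di * a0[idc]) / s2_a0[k]) / prec_g
      e <- rnorm(1, mean_g, sqrt(1 / prec_g))
      gamma[k] <- gamma[k] + e
      a1[idc] <- a1[idc] - e
      a0[idc] <- a0[idc] - e * di
    }
    g_o <- gamma[kk]; a0_o <- a0[cell_pos]; a1_o <- a1[cell_pos]

    # variance components
    res <- y - xb - g_o * (t + delta[ii]) - a0_o - a1_o * t
    for (k in seq_len(K)) {
      id <- obs_k[[k]]
      s2_eps[k] <- 1 / rgamma(1, priors$a_eps + length(id) / 2,
                              priors$b_eps + sum(res[id]^2) / 2)
    }
    s2_d <- 1 / rgamma(1, priors$a_d + n / 2, priors$b_d + sum(delta^2) / 2)
    for (k in seq_len(K)) {
       idc <- cell_k == k
      s2_a0[k] <- 1 / rgamma(1, priors$a_re + sum(idc) / 2,
                             priors$b_re0 + sum(a0[idc]^2) / 2)
      s2_a1[k] <- 1 / rgamma(1, priors$a_re + sum(idc) / 2,
                             priors$b_re1 + sum(a1[idc]^2) / 2)
    }

    if (it > warmup) {
      j <- it - warmup
      draws$beta[j, , ] <- beta
      draws$gamma[j, ] <- gamma
      draws$delta[j, ] <- delta
      draws$s2_eps[j, ] <- s2_eps
      draws$s2_d[j] <- s2_d
      a0_sum <- a0_sum + a0; a1_sum <- a1_sum + a1
    }
  }
  draws$a0_mean <- a0_sum / n_save
  draws$a1_mean <- a1_sum / n_save
  draws$cell_i <- cell_i; draws$cell_k <- cell_k
  draws
}

# Weakly informative conjugate priors. The paper-style model states mean-zero
# normality for delta and the random effects but no priors; these defaults
# are vague relative to the information in a ~150-subject cohort.
ltjmm_priors <- function() {
  list(beta_sd = 10, gamma_sd = 10,
       a_eps = 2, b_eps = 0.001,
       a_d = 2, b_d = 1,
       a_re = 2, b_re0 = 0.0025, b_re1 = 1e-4)
}

# split-R-hat over a draws matrix (iterations x chains)
split_rhat <- function(mat) {
  m <- ncol(mat); nit <- nrow(mat)
  half <- floor(nit / 2)
  chains <- do.call(cbind, lapply(seq_len(m), function(j)
    cbind(mat[seq_len(half), j], mat[(nit - half + 1):nit, j])))
  nh <- nrow(chains); mh <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  B <- nh * var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Fit the latent-time joint mixed-effects model
#'
#' Fits, by MCMC (blocked Gibbs sampling; every full conditional of this
#' linear-Gaussian hierarchy is conjugate), the joint model in which each
#' normalized outcome follows a covariate-adjusted linear trajectory on a
#' per-subject *latent disease time* `t + delta_i`: a time shift shared
#' across outcomes, plus outcome-specific fixed slopes and per-subject
#' random intercepts/slopes. Only PD subjects are modeled. The mean-zero
#' prior on `delta` anchors the latent timescale so that 0 corresponds to
#' the cohort's average disease stage at diagnosis.
#'
#' @param cohort a `long_cohort` (normalized with [normalize_outcomes()];
#'   done automatically when the `value_norm` column is absent).
#' @param spec an [ltjmm_spec()].
#' @param seed integer seed.
#' @return a `latent_time_fit`: posterior summaries `beta`, `gamma`,
#'   `delta` (mean/sd per subject, plus `delta_centered` recentred to the
#'   baseline-visit mean), `sigma_eps`, `sigma_delta`, random-effect
#'   summaries, per-parameter `rhat` (split-R-hat across chains),
#'   `max_rhat`, `converged`, and the spec echo.
#' @export
fit_ltjmm <- function(cohort, spec = ltjmm_spec(), seed = 1L) {
  stopifnot(inherits(cohort, "long_cohort"), inherits(spec, "ltjmm_spec"))
  if (is.null(cohort$observations$value_norm))
    cohort <- normalize_outcomes(cohort, out_of_range = "clamp")
  dat <- ltjmm_data(cohort, spec)
  base_seed <- child_seed(seed, "mcmc")
  chains <- lapply(seq_len(spec$chains), function(cc)
    ltjmm_gibbs(dat, spec$iterations, spec$warmup, seed = base_seed + cc))

  K <- dat$K; p <- dat$p; n <- dat$n
  pool <- function(get) do.call(rbind, lapply(chains, get))
  per_chain <- function(get) vapply(chains, get, numeric(nrow(chains[[1]]$gamma)))

  gamma_draws <- pool(function(ch) ch$gamma)
  beta_mean <- apply(Reduce(`+`, lapply(chains, function(ch) ch$beta)) /
                       length(chains), c(2, 3), mean)
  dimnames(beta_mean) <- list(dat$outcomes, colnames(dat$X))
  gamma_mean <- colMeans(gamma_draws)
  delta_draws <- pool(function(ch) ch$delta)
  delta_mean <- setNames(colMeans(delta_draws), dat$subjects)
  delta_sd <- setNames(apply(delta_draws, 2, sd), dat$subjects)
  sigma_eps <- setNames(sqrt(colMeans(pool(function(ch) ch$s2_eps))), dat$outcomes)
  sigma_delta <- sqrt(mean(unlist(lapply(chains, function(ch) ch$s2_d))))

  rhat <- c(
    setNames(vapply(seq_len(K), function(k)
      split_rhat(per_chain(function(ch) ch$gamma[, k])), 0),
      paste0("gamma[", dat$outcomes, "]")),
    setNames(vapply(seq_len(n), function(i)
      split_rhat(per_chain(function(ch) ch$delta[, i])), 0),
      paste0("delta[", dat$subjects, "]")),
    sigma_delta = split_rhat(per_chain(function(ch) sqrt(ch$s2_d))))
  max_rhat <- max(rhat)
  converged <- max_rhat < spec$rhat_threshold
  if (!converged)
    warning(sprintf("LTJMM not converged: max split-R-hat %.3f >= %.2f",
                    max_rhat, spec$rhat_threshold))
  if (any(gamma_mean < 0))
    warning("negative fitted slope(s) gamma_k: check outcome direction harmonization")

  # recentred delta: baseline-visit mean maps latent time 0 to the cohort's
  # average stage at diagnosis
  delta_centered <- delta_mean - mean(delta_mean)

  re <- data.frame(subject_id = dat$subjects[chains[[1]]$cell_i],
                   outcome = dat$outcomes[chains[[1]]$cell_k],
                   alpha0 = Reduce(`+`, lapply(chains, `[[`, "a0_mean")) / length(chains),
                   alpha1 = Reduce(`+`, lapply(chains, `[[`, "a1_mean")) / length(chains),
                   stringsAsFactors = FALSE)

  structure(list(spec = spec, outcomes = dat$outcomes,
                 covariate_names = colnames(dat$X),
                 beta = beta_mean, gamma = setNames(gamma_mean, dat$outcomes),
                 delta = delta_mean, delta_sd = delta_sd,
                 delta_centered = delta_centered,
                 random_effects = re,
                 sigma_eps = sigma_eps, sigma_delta = sigma_delta,
                 rhat = rhat, max_rhat = max_rhat, converged = converged,
                 n_subjects = n, seed = seed),
            class = "latent_time_fit")
}

#' @export
print.latent_time_fit <- function(x, ...) {
  cat(sprintf("latent_time_fit: %d PD subjects, %d outcomes, %d chains x %d iter\n",
              x$n_subjects, length(x$outcomes), x$spec$chains, x$spec$iterations))
  cat(sprintf("  max split-R-hat %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  cat("  gamma:", paste(sprintf("%s=%.3f", x$outcomes, x$gamma), collapse = ", "), "\n")
  invisible(x)
}

#' Per-visit latent disease times
#'
#' `latent_time = t + E[delta_i]`: observed time since diagnosis shifted by
#' the subject's posterior-mean time shift.
#'
#' @param fit a `latent_time_fit`.
#' @param cohort the cohort the fit was computed on.
#' @param warn_not_converged require convergence unless overridden.
#' @return data.frame (subject_id, time, latent_time) for fitted subjects,
#'   one row per distinct visit time; attribute `delta_population_mean`.
#' @export
latent_times <- function(fit, cohort, warn_not_converged = TRUE) {
  stopifnot(inherits(fit, "latent_time_fit"))
  if (!fit$converged && warn_not_converged)
    warning("using latent times from a non-converged fit")
  obs <- cohort$observations
  obs <- obs[obs$subject_id %in% names(fit$delta), c("subject_id", "time")]
  obs <- unique(obs)
  missing <- setdiff(unique(obs$subject_id), names(fit$delta))
  if (length(missing)) stop_bagpd("subjects absent from fit: %s",
                                  paste(missing, collapse = ", "))
  obs$latent_time <- obs$time + fit$delta[obs$subject_id]
  attr(obs, "delta_population_mean") <- mean(fit$delta)
  rownames(obs) <- NULL
  obs
}

#' Kendall tau-b rank correlation
#'
#' Pair-counting implementation with tie correction:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where `n0 = n(n-1)/2` and
#' `n1`, `n2` count pairs tied on `x` and `y`.
#'
#' @param x,y numeric/ordinal vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  sx <- sign(outer(x, x, `-`)); sy <- sign(outer(y, y, `-`))
  ut <- upper.tri(sx)
  C <- sum(sx[ut] * sy[ut] > 0)
  D <- sum(sx[ut] * sy[ut] < 0)
  n0 <- n * (n - 1) / 2
  n1 <- sum(sx[ut] == 0)
  n2 <- sum(sy[ut] == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) stop_bagpd("tau-b undefined: a variable is constant")
  (C - D) / den
}

#' Validate latent times against an ordinal staging variable
#'
#' Computes Kendall tau-b of an ordinal disease stage (e.g. H&Y) with
#' (I) latent disease time and (II) raw time since diagnosis, and tests the
#' difference with a subject-level bootstrap (resampling subjects with
#' replacement; two-sided percentile p for tau_latent - tau_time = 0).
#'
#' @param latent numeric latent disease times, one per visit.
#' @param staging ordinal stage per visit (>= 2 observed levels).
#' @param t_since_dx time since diagnosis per visit.
#' @param subject_id subject identifier per visit (bootstrap resampling
#'   unit); default treats rows as independent subjects.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return a `validation_report`: `tau_latent`, `tau_time`, `diff`,
#'   `p_value`, `n_boot`.
#' @export
validate_latent_time <- function(latent, staging, t_since_dx,
                                 subject_id = seq_along(latent),
                                 n_boot = 1000L, seed = 1L) {
  if (length(unique(staging)) < 2) stop_bagpd("staging must have >= 2 levels")
  tau_l <- kendall_tau_b(staging, latent)
  tau_t <- kendall_tau_b(staging, t_since_dx)
  ids <- unique(subject_id)
  rows_of <- split(seq_along(latent), subject_id)
  diffs <- with_seed(child_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(rows_of[sample(as.character(ids), length(ids), replace = TRUE)],
                     use.names = FALSE)
      st <- staging[take]
      if (length(unique(st)) < 2) return(NA_real_)
      kendall_tau_b(st, latent[take]) - kendall_tau_b(st, t_since_dx[take])
    }, 0)
  })
  diffs <- diffs[!is.na(diffs)]
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(max(p, 1 / length(diffs)), 1)
  structure(list(tau_latent = tau_l, tau_time = tau_t,
                 diff = tau_l - tau_t, p_value = p, n_boot = length(diffs)),
            class = "validation_report")
}
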