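# Shared fixtures, built in code at test time.

# small cohort + matching features for pipeline tests
small_world <- function(n_hc = 60, n_pd = 40, seed = 42, ...) {
  sim <- simulate_cohort(sim_config(n_hc = n_hc, n_pd = n_pd, ...), seed = seed)
  sim
}

hc_baseline_grid <- function(sim, fg) {
  s <- sim$cohort$subjects
  keep <- fg$scans$subject_id %in% s$subject_id[s$group == "HC"] &
    !duplicated(fg$scans$subject_id)
  bagpd:::subset_grid(fg, keep)
}

# noise-free deterministic cohort: epsilon = delta = random effects = 0,
# all subtype multipliers 1
noisefree_config <- function(n_hc = 5, n_pd = 10) {
  specs <- default_outcomes()
  for (i in seq_along(specs)) specs[[i]]$noise_sd <- 0
  sim_config(n_hc = n_hc, n_pd = n_pd, outcomes = specs,
             delta_sd = 0, alpha0_sd = 0, alpha1_sd = 0,
             slope_multipliers = c(fast = 1, slow = 1, unknown = 1),
             clamp_values = FALSE)
}

# brute-force Kendall tau-b over all pairs with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx * sy > 0) C <- C + 1
    if (sx * sy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# definition-based BH oracle: p_adj(i) = min_{j:rank>=rank_i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  adj[order(o)]
}

# Efron partial log-likelihood by risk-set enumeration (delayed entry)
oracle_cox_loglik <- function(beta, entry, exit, event, Xmat) {
  eta <- as.vector(Xmat %*% beta)
  w <- exp(eta)
  ll <- 0
  for (tt in sort(unique(exit[event]))) {
    dead <- which(event & exit == tt)
    risk <- which(entry < tt & exit >= tt)
    d <- length(dead)
    sum_risk <- sum(w[risk]); sum_dead <- sum(w[dead])
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
  }
  ll
}

# partial correlation via the inverse-correlation-matrix formula
oracle_partial_r <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  P <- solve(cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# direct separable discrete-Gaussian convolution (interior oracle)
oracle_gauss_conv <- function(arr, sigma_vox) {
  rad <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-rad:rad) / sigma_vox)^2); k <- k / sum(k)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    src <- out
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      acc <- 0; wsum <- 0
      for (o in -rad:rad) {
        idx <- c(i, j, l); idx[ax] <- idx[ax] + o
        if (idx[ax] >= 1 && idx[ax] <= d[ax]) {
          acc <- acc + k[o + rad + 1] * src[idx[1], idx[2], idx[3]]
          wsum <- wsum + k[o + rad + 1]
        }
      }
      out[i, j, l] <- acc / wsum
    }
  }
  out
}
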