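# Shared fixture builders: everything is generated in code at test time.

# A small complete feature matrix with two batches.
tiny_fm <- function(n = 12, p = 4, seed = 42, n_batches = 2) {
  set.seed(seed)
  values <- matrix(exp(rnorm(n * p, 2, 0.5)), n, p,
                   dimnames = list(sprintf("S%02d", seq_len(n)),
                                   sprintf("M%02d", seq_len(p))))
  feature_matrix(values, batch = rep_len(sprintf("B%d", seq_len(n_batches)), n))
}

# A small cohort + metabolome pair on the adolescent design.
small_scene <- function(seed = 1, n = 120, p = 30, n_truth = 3, ...) {
  cfg <- standard_sim_config(seed = seed, n = n, p = p, n_truth = n_truth, ...)
  cohort <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, cohort)
  list(cfg = cfg, cohort = cohort, fm = gm$fm, truth = gm$truth)
}

# Independent brute-force oracle for the elbow rule: scan every drop,
# qualify sharp drops (local maxima above the documented prominence), take
# the last; otherwise the single largest drop.
elbow_oracle <- function(f) {
  d <- f[-length(f)] - f[-1]
  thr <- max(mean(d), 0.8 * max(d))
  last <- 0
  for (i in seq_along(d)) {
    left_ok <- i == 1 || d[i] >= d[i - 1]
    right_ok <- i == length(d) || d[i] >= d[i + 1]
    if (d[i] > thr && left_ok && right_ok) last <- i
  }
  if (last > 0) last else which.max(d)
}

# Direct-regression VIF oracle.
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Columns made exactly orthogonal (after centring) via QR.
orthogonal_cols <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1), drop = FALSE]
  colnames(M) <- sprintf("M%02d", seq_len(p))
  M * sqrt(n)
}
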