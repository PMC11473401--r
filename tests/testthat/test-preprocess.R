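# Preprocessing: filtering, imputation, standardization, batch correction,
# covariate KNN.

test_that("the consumer-missingness filter applies a strict > rule per food", {
  vals <- matrix(exp(rnorm(100 * 3, 2, 0.3)), 100, 3,
                 dimnames = list(sprintf("S%03d", 1:100), c("A", "B", "C")))
  # feature A: 31/100 missing among ssb consumers; feature B: exactly 30;
  # feature C: complete
  vals[1:31, "A"] <- NA
  vals[1:30, "B"] <- NA
  fm <- feature_matrix(vals, batch = rep("B1", 100))
  consumers <- list(ssb = sprintf("S%03d", 1:100),
                    as = sprintf("S%03d", 32:100)) # A complete among as-consumers
  fr <- filter_missing(fm, consumers, threshold = 0.30)
  expect_false("A" %in% fr$retained$ssb) # 31% > 30% -> dropped for ssb
  expect_true("B" %in% fr$retained$ssb) # exactly 30% -> retained
  expect_true("A" %in% fr$retained$as) # retention is food-specific
  expect_true(all(c("A", "B", "C") %in% colnames(fr$fm$values)))
  expect_identical(fr$dropped, character(0))
  # counting oracle: 2 missing among 6 consumers = 33.3% -> dropped
  v2 <- matrix(exp(rnorm(10)), 10, 1, dimnames = list(sprintf("s%02d", 1:10), "X"))
  v2[1:2, 1] <- NA
  fm2 <- feature_matrix(v2, batch = rep("B1", 10))
  fr2 <- filter_missing(fm2, list(ssb = sprintf("s%02d", 1:6)), 0.30)
  expect_identical(fr2$retained$ssb, character(0))
  expect_error(filter_missing(fm2, list(ssb = character(0))), "ssb")
})

test_that("half-minimum imputation fills each gap with half the batch minimum", {
  vals <- matrix(c(2, 4, NA, 8, 10, NA), 3, 2,
                 dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  fm <- feature_matrix(vals, batch = c("B1", "B1", "B1"))
  out <- impute_half_min(fm)
  expect_equal(unname(out$values[3, ]), c(1, 4))
  # per-batch minima: oracle = per-batch min scan
  v2 <- matrix(exp(rnorm(8 * 2, 1, 0.4)), 8, 2,
               dimnames = list(sprintf("s%d", 1:8), c("A", "B")))
  v2[c(1, 5), 1] <- NA
  batch <- rep(c("B1", "B2"), each = 4)
  fm2 <- feature_matrix(v2, batch = batch)
  out2 <- impute_half_min(fm2)
  expect_equal(out2$values[1, 1], min(v2[2:4, 1], na.rm = TRUE) / 2)
  expect_equal(out2$values[5, 1], min(v2[6:8, 1], na.rm = TRUE) / 2)
  # observed cells untouched; complete input returned unchanged
  obs <- !is.na(v2)
  expect_identical(out2$values[obs], v2[obs])
  fm3 <- tiny_fm()
  expect_equal(impute_half_min(fm3)$values, fm3$values)
  # fully missing (feature, batch) pair is an error naming the pair
  v4 <- v2
  v4[1:4, 2] <- NA
  expect_error(impute_half_min(feature_matrix(v4, batch = batch)), "B, B1")
})

test_that("censored-quantile imputation draws from the fitted left tail", {
  set.seed(21)
  n <- 2000
  z <- rnorm(n)
  vals <- matrix(exp(z), n, 1, dimnames = list(sprintf("s%04d", 1:n), "A"))
  fm <- feature_matrix(vals, batch = rep("B1", n))
  fmc <- inject_missingness(fm, 0.2)
  out <- impute_censored_quantile(fmc, seed = 3)
  imp <- log(out$values[is.na(fmc$values[, 1]), 1])
  tail_mean <- -dnorm(qnorm(0.2)) / 0.2 # E[Z | Z < q_0.2] = -1.40
  expect_lt(abs(mean(imp) - tail_mean), 0.15)
  # observed cells untouched, no remaining missing
  obs <- !is.na(fmc$values)
  expect_identical(out$values[obs], fmc$values[obs])
  expect_false(anyNA(out$values))
  # no missing -> identity; constant feature -> half-min fallback with warning
  expect_equal(impute_censored_quantile(fm)$values, fm$values)
  vc <- matrix(c(2, 2, 2, NA), 4, 1, dimnames = list(sprintf("s%d", 1:4), "A"))
  expect_warning(outc <- impute_censored_quantile(
    feature_matrix(vc, batch = rep("B1", 4))), "fallback")
  expect_equal(unname(outc$values[4, 1]), 1)
})

test_that("forest imputation reconstructs a duplicated feature", {
  set.seed(31)
  n <- 300
  base <- exp(rnorm(n, 2, 0.6))
  vals <- cbind(A = base, B = base, C = exp(rnorm(n)), D = exp(rnorm(n)))
  rownames(vals) <- sprintf("s%03d", 1:n)
  hidden <- sample(n, 30)
  masked <- vals
  masked[hidden, "B"] <- NA
  fm <- feature_matrix(masked, batch = rep("B1", n))
  out <- impute_forest(fm, seed = 5, num_trees = 300)
  expect_false(anyNA(out$values))
  expect_gt(cor(log(out$values[hidden, "B"]), log(base[hidden])), 0.95)
  obs <- !is.na(masked)
  expect_identical(out$values[obs], masked[obs])
  # no missing -> identity
  fm2 <- tiny_fm()
  expect_equal(impute_forest(fm2, seed = 1)$values, fm2$values)
})

test_that("log-standardization matches the population-SD hand computation", {
  vals <- matrix(c(1, exp(1), exp(2)), 3, 1,
                 dimnames = list(c("s1", "s2", "s3"), "A"))
  fm <- feature_matrix(vals, batch = rep("B1", 3), stage = "imputed")
  out <- log_standardize(fm)
  expect_equal(unname(out$values[, 1]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # per-feature mean 0 and population SD 1 by construction
  fm2 <- tiny_fm(n = 40, p = 6)
  fm2$stage <- "imputed"
  out2 <- log_standardize(fm2)
  expect_lt(max(abs(colMeans(out2$values))), 1e-12)
  psd <- apply(out2$values, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(psd), rep(1, 6), tolerance = 1e-12)
  # constant column dropped with a warning, others untouched
  v3 <- cbind(out2$values[, 0], K = rep(2, 40), exp(out2$values[, 1, drop = FALSE]))
  colnames(v3) <- c("K", "A")
  fm3 <- feature_matrix(v3, batch = fm2$batch, stage = "imputed")
  expect_warning(out3 <- log_standardize(fm3), "K")
  expect_identical(colnames(out3$values), "A")
})

test_that("batch correction nulls injected location and scale effects", {
  set.seed(41)
  n <- 400
  batch <- rep(c("B1", "B2"), each = n / 2)
  z <- rnorm(n)
  z <- z + ifelse(batch == "B1", 1, -1) # location
  z <- z * ifelse(batch == "B1", 2, 0.5) # scale
  vals <- matrix(exp(z), n, 1, dimnames = list(sprintf("s%03d", 1:n), "A"))
  fm <- log_standardize(feature_matrix(vals, batch = batch, stage = "imputed"))
  out <- correct_batch(fm)
  m <- tapply(out$values[, 1], batch, mean)
  expect_lt(abs(m[1] - m[2]), 1e-10)
  s <- tapply(out$values[, 1], batch, sd)
  expect_gt(s[1] / s[2], 0.9)
  expect_lt(s[1] / s[2], 1.1)
  # monotone within batch: cross-sample ordering preserved
  for (b in c("B1", "B2")) {
    expect_identical(order(out$values[batch == b, 1]),
                     order(fm$values[batch == b, 1]))
  }
  # single batch: output equals input up to re-centring
  fm1 <- log_standardize(tiny_fm(n = 10, p = 3, n_batches = 1))
  out1 <- correct_batch(fm1)
  expect_equal(out1$values, sweep(fm1$values, 2, colMeans(fm1$values)),
               tolerance = 1e-12)
  # a batch with < 2 samples is an error
  fmb <- log_standardize(feature_matrix(vals, batch = c("Bx", batch[-1]),
                                        stage = "imputed"))
  expect_error(correct_batch(fmb), "fewer than 2")
})

test_that("the pipeline stage order is enforced", {
  fm <- tiny_fm()
  expect_error(correct_batch(fm), "pipeline order")
  std <- log_standardize(impute_half_min(fm))
  expect_error(filter_missing(std, list(ssb = rownames(std$values))),
               "pipeline order")
  expect_error(impute_half_min(std), "pipeline order")
  expect_error(log_standardize(correct_batch(std)), "pipeline order")
})

test_that("covariate KNN imputes from the nearest neighbours under Gower distance", {
  cfg <- sim_config(n_participants = 60, design = "adolescent_single",
                    n_features = 2, covariate_missing_rate = 0, seed = 11)
  co <- generate_cohort(cfg)
  expect_identical(knn_impute_covariates(co, k = 10), co) # no missing
  # exhaustive-distance oracle: 11 clones of one row, target missing in one
  co2 <- co
  co2[1:11, c("sex", "age", "energy", "met_hours", "alcohol", "smoking")] <-
    co2[rep(1, 11), c("sex", "age", "energy", "met_hours", "alcohol", "smoking")]
  co2$birthweight[1:11] <- 3300
  co2$birthweight[1] <- NA
  out <- knn_impute_covariates(co2, k = 10)
  expect_equal(out$birthweight[1], 3300)
  expect_false(anyNA(out[, c("birthweight", "met_hours", "alcohol", "smoking")]))
  # categorical majority with alphabetical tie-break
  co3 <- co
  co3[1:11, c("sex", "age", "energy", "met_hours", "birthweight", "alcohol")] <-
    co3[rep(1, 11), c("sex", "age", "energy", "met_hours", "birthweight", "alcohol")]
  co3$smoking[2:6] <- "never"
  co3$smoking[7:11] <- "former"
  co3$smoking[1] <- NA
  out3 <- knn_impute_covariates(co3, k = 10)
  expect_equal(as.character(out3$smoking[1]), "former")
  expect_error(knn_impute_covariates(co, k = 60), "n - 1")
})
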