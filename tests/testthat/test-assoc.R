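# Association models: OLS, random-intercept mixed models, BH adjustment.

make_adolescent_data <- function(seed = 1, n = 200, beta = 0.001,
                                 sigma = 0) {
  cfg <- sim_config(n_participants = n, design = "adolescent_single",
                    n_features = 2, covariate_missing_rate = 0, seed = seed)
  co <- generate_cohort(cfg)
  set.seed(seed + 1000)
  d <- as.data.frame(co)
  d$M1 <- beta * d$ssb + 0.01 * d$age + 0.2 * (d$sex == "male") +
    1e-4 * d$energy + rnorm(nrow(d), 0, sigma)
  d
}

test_that("OLS recovers a noiseless exposure coefficient to machine precision", {
  d <- make_adolescent_data(beta = 0.001, sigma = 0)
  spec <- model_spec("M1", "ssb", "adolescent_single")
  row <- fit_linear(spec, d)
  expect_equal(row$beta, 0.001, tolerance = 1e-12)
  expect_identical(row$model, "linear")
  expect_equal(row$n, nrow(d))
  expect_true(row$ci_low <= row$beta && row$beta <= row$ci_high)
})

test_that("aliased designs raise an error naming the offending column", {
  d <- make_adolescent_data(sigma = 0.1)
  d$energy <- d$ssb # covariate duplicates the exposure
  spec <- model_spec("M1", "ssb", "adolescent_single")
  expect_error(fit_linear(spec, d), "rank-deficient")
})

test_that("missing model cells and mismatched covariate sets are rejected", {
  d <- make_adolescent_data(sigma = 0.1)
  d$met_hours[3] <- NA
  spec <- model_spec("M1", "ssb", "adolescent_single")
  expect_error(fit_linear(spec, d), "missing cells")
  expect_error(model_spec("M1", "ssb", "adolescent_single",
                          covariates = c("age", "sex", "energy")), "locked")
  expect_error(model_spec("M1", "ssb", "adolescent_single",
                          random_intercept = TRUE), "repeated occasions")
  expect_identical(covariates_for_design("children_repeated"),
                   c("age", "sex", "energy"))
  expect_true(all(c("n_assessments", "time_gap") %in%
                    covariates_for_design("adult_plasma")))
})

test_that("null-feature p-values are uniform", {
  set.seed(61)
  n <- 200
  reps <- 800
  cfg <- sim_config(n_participants = n, design = "adolescent_single",
                    n_features = 2, covariate_missing_rate = 0, seed = 62)
  co <- as.data.frame(generate_cohort(cfg))
  spec <- model_spec("M1", "ssb", "adolescent_single")
  ps <- vapply(seq_len(reps), function(i) {
    co$M1 <- rnorm(n)
    fit_linear(spec, co)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("exposure rescaling divides the estimate and CI exactly", {
  d <- make_adolescent_data(sigma = 0.3)
  spec <- model_spec("M1", "ssb", "adolescent_single")
  r1 <- fit_linear(spec, d)
  d2 <- d
  d2$ssb <- d2$ssb * 10
  r2 <- fit_linear(spec, d2)
  expect_equal(r2$beta, r1$beta / 10, tolerance = 1e-12)
  expect_equal(r2$ci_low, r1$ci_low / 10, tolerance = 1e-12)
  expect_equal(r2$ci_high, r1$ci_high / 10, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-9)
})

make_children_data <- function(seed, n = 150, beta = 0.002, sd_u = 0.8,
                               sigma = 1) {
  cfg <- sim_config(n_participants = n, design = "children_repeated",
                    n_features = 2, covariate_missing_rate = 0, seed = seed)
  co <- as.data.frame(generate_cohort(cfg))
  set.seed(seed + 5000)
  u <- rnorm(n, 0, sd_u)
  co$M1 <- beta * co$ssb + 0.02 * co$age +
    u[as.integer(factor(co$participant_id))] + rnorm(nrow(co), 0, sigma)
  co
}

test_that("the random-intercept estimate solves the GLS equations", {
  d <- make_children_data(seed = 71)
  spec <- model_spec("M1", "ssb", "children_repeated")
  row <- suppressWarnings(fit_mixed(spec, d))
  expect_identical(row$model, "mixed")
  vc <- attr(row, "varcomp")
  # closed-form GLS at the fitted variance components
  Xmm <- model.matrix(~ ssb + age + sex + energy, data = d)
  pid <- factor(d$participant_id)
  Z <- model.matrix(~ pid - 1)
  V <- vc[["participant_id"]] * tcrossprod(Z) + vc[["Residual"]] * diag(nrow(d))
  beta_gls <- solve(crossprod(Xmm, solve(V, Xmm)), crossprod(Xmm, solve(V, d$M1)))
  expect_equal(row$beta, unname(beta_gls["ssb", 1]), tolerance = 1e-8)
})

test_that("zero between-participant variance reduces the mixed model to OLS", {
  d <- make_children_data(seed = 77, sd_u = 0)
  spec <- model_spec("M1", "ssb", "children_repeated")
  row <- suppressWarnings(fit_mixed(spec, d))
  spec_ols <- model_spec("M1", "ssb", "children_repeated",
                         random_intercept = FALSE)
  ols <- fit_linear(spec_ols, d)
  expect_equal(row$beta, ols$beta, tolerance = 1e-6)
  expect_error(suppressWarnings(fit_mixed(spec, d, fallback = FALSE)),
               "singular")
})

test_that("the mixed model recovers a planted exposure effect on average", {
  est <- vapply(1:50, function(s) {
    d <- make_children_data(seed = 100 + s, n = 100, beta = 0.002)
    suppressWarnings(fit_mixed(model_spec("M1", "ssb", "children_repeated"), d)$beta)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.002), 2e-4)
})

test_that("BH adjustment reproduces the step-up rule and controls monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # manual step-up oracle on random vectors
  set.seed(81)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    m <- length(p)
    o <- order(p)
    manual <- numeric(m)
    manual[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
    expect_equal(bh_adjust(p), pmin(manual, 1))
    expect_true(all(bh_adjust(p) >= p - 1e-15))
  }
})

test_that("associate builds a BH-adjusted table over consensus features", {
  sc <- small_scene(seed = 91, n = 150, p = 12, n_truth = 2)
  co <- generate_adiposity(sc$cohort, sc$fm, sc$cfg)
  fm <- log_standardize(sc$fm)
  co_i <- knn_impute_covariates(co, k = 10)
  tab <- associate(fm, co_i, colnames(fm$values)[1:6], "ssb",
                   "adolescent_single")
  expect_s3_class(tab, "association_table")
  expect_identical(names(tab), c("food", "feature", "beta", "ci_low",
                                 "ci_high", "p", "q", "model", "n"))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_equal(tab$q, bh_adjust(tab$p))
  # the block-OLS fast path agrees with the per-feature fit exactly
  d <- cbind(as.data.frame(co_i), as.data.frame(fm$values))
  for (f in colnames(fm$values)[1:3]) {
    r <- fit_linear(model_spec(f, "ssb", "adolescent_single"), d)
    i <- match(f, tab$feature)
    expect_equal(tab$beta[i], r$beta, tolerance = 1e-12)
    expect_equal(tab$ci_low[i], r$ci_low, tolerance = 1e-12)
    expect_equal(tab$p[i], r$p, tolerance = 1e-10)
  }
})
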