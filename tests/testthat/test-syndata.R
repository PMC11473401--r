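# Synthetic cohort and metabolome generator.

test_that("identical configurations reproduce every artifact bit-for-bit", {
  cfg <- standard_sim_config(seed = 7, n = 60, p = 20, n_truth = 2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ga <- generate_metabolome(cfg, a)
  gb <- generate_metabolome(cfg, b)
  expect_identical(ga, gb)
  expect_identical(generate_adiposity(a, ga$fm, cfg),
                   generate_adiposity(b, gb$fm, cfg))
  expect_identical(inject_missingness(ga$fm, cfg),
                   inject_missingness(gb$fm, cfg))
})

test_that("the copula calibration hits the target SSB-AS correlation", {
  cfg <- sim_config(n_participants = 5000, design = "adolescent_single",
                    n_features = 2, intake_correlation = 0.65, seed = 1)
  co <- generate_cohort(cfg)
  r <- cor(co$ssb, co$as)
  expect_gte(r, 0.60)
  expect_lte(r, 0.70)
})

test_that("degenerate intake mixtures behave as stated", {
  ip <- list(lncsb = list(p_zero = 1 - 1e-12, meanlog = 5, sdlog = 1),
             ssb = list(p_zero = 0.3, meanlog = 5.57, sdlog = 1.2),
             as = list(p_zero = 0.02, meanlog = log(62.2), sdlog = 0.68))
  cfg <- sim_config(n_participants = 400, design = "adolescent_single",
                    n_features = 2, intake_params = ip, seed = 3)
  co <- generate_cohort(cfg)
  expect_true(all(co$lncsb == 0))
  expect_equal(co$sb, co$ssb + co$lncsb)
})

test_that("the empirical added-sugar median matches the closed-form mixture quantile", {
  cfg <- sim_config(n_participants = 2000, design = "adolescent_single",
                    n_features = 2, seed = 2)
  co <- generate_cohort(cfg)
  ip <- cfg$intake_params$as
  med <- ziln_moments(ip$p_zero, ip$meanlog, ip$sdlog)$median
  expect_equal(ziln_quantile(0.5, ip$p_zero, ip$meanlog, ip$sdlog), med)
  expect_lt(abs(median(co$as) - med) / med, 0.10)
})

test_that("a noiseless planted effect is recovered by OLS to machine precision", {
  cfg <- sim_config(n_participants = 80, design = "adolescent_single",
                    n_features = 5, true_effects = list(ssb = data.frame(
                      feature = 3, beta = 0.002)),
                    noise_sd = 0, batch_shift_sd = 0, batch_scale_sd = 0,
                    covariate_missing_rate = 0, seed = 5)
  co <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, co)
  L <- log(gm$fm$values[, 3])
  sexn <- as.numeric(co$sex == "male")
  fit <- lm(L ~ co$ssb + I(co$age - mean(co$age)) + sexn)
  expect_equal(unname(coef(fit)[2]), 0.002, tolerance = 1e-10)
})

test_that("null features carry no intake association", {
  cfg <- sim_config(n_participants = 2000, design = "adolescent_single",
                    n_features = 20, noise_sd = 1, batch_shift_sd = 0,
                    batch_scale_sd = 0, covariate_missing_rate = 0, seed = 8)
  co <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, co)
  cors <- abs(cor(log(gm$fm$values), co$ssb))
  expect_lt(max(cors), 3 / sqrt(2000))
})

test_that("the default feature scale is honoured", {
  cfg <- sim_config(n_participants = 15, design = "adolescent_single",
                    n_features = 1400, intake_correlation = 0.65, seed = 1)
  co <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, co)
  expect_identical(dim(gm$fm$values), c(15L, 1400L))
})

test_that("left censoring is strictly left-tail at the configured rate", {
  cfg <- sim_config(n_participants = 1000, design = "adolescent_single",
                    n_features = 10, lod_quantile = 0.3, seed = 4)
  co <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, co)
  fmc <- inject_missingness(gm$fm, cfg)
  frac <- colMeans(is.na(fmc$values))
  expect_true(all(frac >= 0.29 & frac <= 0.31))
  for (j in seq_len(10)) {
    masked <- gm$fm$values[is.na(fmc$values[, j]), j]
    observed <- fmc$values[!is.na(fmc$values[, j]), j]
    expect_lte(max(masked), min(observed))
  }
  # no censoring when the quantile is zero
  cfg0 <- sim_config(n_participants = 50, design = "adolescent_single",
                     n_features = 4, lod_quantile = 0, seed = 4)
  co0 <- generate_cohort(cfg0)
  gm0 <- generate_metabolome(cfg0, co0)
  expect_false(anyNA(inject_missingness(gm0$fm, cfg0)$values))
  expect_error(inject_missingness(gm0$fm, 1), "lod_quantile")
})

test_that("children design has two occasions with within-participant correlation", {
  cfg <- sim_config(n_participants = 150, design = "children_repeated",
                    n_features = 30, batch_shift_sd = 0, batch_scale_sd = 0,
                    seed = 6)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 300)
  expect_true(all(table(co$participant_id) == 2))
  expect_equal(diff(co$age[1:2]), 1)
  gm <- generate_metabolome(cfg, co)
  L <- log(gm$fm$values)
  icc <- mean(sapply(seq_len(30), function(j) {
    cor(L[co$occasion == 1, j], L[co$occasion == 2, j])
  }))
  expect_gt(icc, 0.25)
  expect_lt(icc, 0.55)
})

test_that("adiposity outcomes exist, respond to planted effects and stay null otherwise", {
  # three outcomes per row, exact noiseless recovery
  cfg <- sim_config(n_participants = 100, design = "adolescent_single",
                    n_features = 6,
                    adiposity_effects = list(bmi = data.frame(feature = 2, coef = 1.5)),
                    adiposity_noise_sd = 0, adiposity_shared_sd = 0,
                    batch_shift_sd = 0,
                    batch_scale_sd = 0, covariate_missing_rate = 0, seed = 9)
  co <- generate_cohort(cfg)
  gm <- generate_metabolome(cfg, co)
  co <- generate_adiposity(co, gm$fm, cfg)
  expect_true(all(c("bmi", "bf_pct", "wc") %in% names(co)))
  Z <- scale(log(gm$fm$values))
  sexn <- as.numeric(co$sex == "male")
  en <- scale(log(co$energy))[, 1]
  fit <- lm(co$bmi ~ Z[, 2] + I(co$age - mean(co$age)) + sexn + en)
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 1e-10)
  # null adiposity: slope CI covers zero
  cfg0 <- sim_config(n_participants = 1500, design = "adolescent_single",
                     n_features = 3, covariate_missing_rate = 0, seed = 10)
  co0 <- generate_cohort(cfg0)
  gm0 <- generate_metabolome(cfg0, co0)
  co0 <- generate_adiposity(co0, gm0$fm, cfg0)
  f0 <- lm(co0$bmi ~ log(gm0$fm$values[, 1]))
  ci <- confint(f0)[2, ]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
  # referencing an absent feature errors
  cfg_bad <- cfg0
  cfg_bad$adiposity_effects <- list(bmi = data.frame(feature = 99, coef = 1))
  expect_error(generate_adiposity(co0, gm0$fm, cfg_bad), "absent")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 5, intake_correlation = 0.65),
               "too small")
  expect_error(sim_config(n_participants = 50, n_features = 10,
                          true_effects = list(ssb = data.frame(feature = 11, beta = 1))),
               "out of range")
  expect_error(sim_config(n_participants = 50, n_features = 10,
                          true_effects = list(ssb = data.frame(feature = 2, beta = 1),
                                              as = data.frame(feature = 2, beta = 1))),
               "conflicting")
  expect_error(sim_config(n_participants = 50, lod_quantile = 1), "lod_quantile")
})
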