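# Synthetic cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: zero-inflated right-skewed beverage/sugar intakes with a
# Gaussian-copula coupling between sugar-sweetened beverages (SSB) and added
# sugar (AS); log-normal metabolite intensities carrying linear intake signal
# on the standardized-log scale; additive/multiplicative analytical batch
# effects; left-censored (detection-limit) missingness; and adiposity
# outcomes driven by a subset of the truly food-associated features.

.designs <- c("children_repeated", "adolescent_single", "adult_plasma")
.foods <- c("lncsb", "ssb", "sb", "as")
.outcomes <- c("bmi", "bf_pct", "wc")

# Cohort-level defaults keyed by design: sample size, median age at
# collection, median total energy intake (kcal/d) and baseline adiposity.
.design_defaults <- list(
  children_repeated = list(n = 297L, age = 7.0, energy = 1530, occasions = 2L,
                           bmi = 15.8, bf = 17.3, wc = 56),
  adolescent_single = list(n = 339L, age = 18.0, energy = 2130, occasions = 1L,
                           bmi = 21.9, bf = 22.6, wc = 74),
  adult_plasma = list(n = 195L, age = 18.1, energy = 1980, occasions = 1L,
                      bmi = 22.2, bf = 23.6, wc = 76)
)

# Default intake distributions (g/d), matched to the adolescent marginals:
# AS median ~62 g/d with interquartile range ~36-90 and essentially no
# non-consumers; SSB median ~133 g/d with ~30% zero days; LNCSB mostly zero.
.default_intake_params <- list(
  lncsb = list(p_zero = 0.60, meanlog = log(150), sdlog = 1.0),
  ssb = list(p_zero = 0.30, meanlog = 5.57, sdlog = 1.2),
  as = list(p_zero = 0.02, meanlog = log(62.2), sdlog = 0.68)
)

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator into a validated object. Defaults
#' reproduce the adolescent study arm: 339 participants with a single urine
#' collection, 1400 metabolite features across 4 analytical batches, an
#' SSB-AS intake correlation of 0.65, and 10% missingness in the lifestyle
#' covariates.
#'
#' @param n_participants number of participants (>= 1).
#' @param design sampling design: `"children_repeated"` (two urine
#'   collections ~1 y apart, participant-level random intercepts),
#'   `"adolescent_single"` (one urine collection) or `"adult_plasma"` (one
#'   plasma draw preceded by 3-6 dietary assessments).
#' @param n_features number of metabolite features.
#' @param n_batches number of analytical batches.
#' @param true_effects named list `food -> data.frame(feature, beta)` of
#'   planted intake effects; `feature` is a column index, `beta` the slope of
#'   the standardized-log intensity per g/d of intake.
#' @param intake_params named list per food (`lncsb`, `ssb`, `as`), each with
#'   `p_zero` (zero-inflation probability), `meanlog`, `sdlog`.
#' @param intake_correlation target Pearson correlation between raw SSB and
#'   AS intakes, achieved through a calibrated Gaussian copula.
#' @param lod_quantile per-feature left-censoring quantile in \[0, 1):
#'   scalar or vector of length `n_features`.
#' @param batch_shift_sd,batch_scale_sd standard deviations of the additive
#'   location shift and of the log multiplicative scale applied per
#'   (batch, feature) on the log-intensity scale.
#' @param adiposity_effects named list `outcome -> data.frame(feature, coef)`
#'   of planted metabolite effects on the adiposity outcomes (`bmi`,
#'   `bf_pct`, `wc`), per SD of standardized-log intensity.
#' @param covariate_missing_rate fraction of cells masked in the imputable
#'   covariates (birthweight, physical activity, alcohol, smoking).
#' @param adiposity_shared_sd SD of the latent per-participant adiposity
#'   factor shared by the three outcomes (on each outcome's scaled-SD
#'   metric); induces the moderate positive correlation among BMI, body-fat
#'   percentage and waist circumference that the correlation-adjusted
#'   significance threshold relies on.
#' @param noise_sd residual SD of log feature intensities.
#' @param icc intra-class correlation of features (and outcomes) across the
#'   two occasions of the children design.
#' @param adiposity_noise_sd residual SD of the adiposity outcomes (on each
#'   outcome's native scale).
#' @param seed master RNG seed; fixes every generated artifact bit-for-bit.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 50, n_features = 20, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
sim_config <- function(n_participants = 339,
                       design = c("adolescent_single", "children_repeated", "adult_plasma"),
                       n_features = 1400,
                       n_batches = 4,
                       true_effects = list(),
                       intake_params = .default_intake_params,
                       intake_correlation = 0.65,
                       lod_quantile = 0.1,
                       batch_shift_sd = 0.3,
                       batch_scale_sd = 0.1,
                       adiposity_effects = list(),
                       covariate_missing_rate = 0.1,
                       adiposity_shared_sd = 0.45,
                       noise_sd = 1,
                       icc = 0.4,
                       adiposity_noise_sd = 2,
                       seed = 1) {
  design <- match.arg(design)
  check_count(n_participants, "n_participants")
  check_count(n_features, "n_features")
  check_count(n_batches, "n_batches")
  check_prob(intake_correlation, "intake_correlation", upper_open = FALSE)
  check_prob(lod_quantile, "lod_quantile")
  check_prob(covariate_missing_rate, "covariate_missing_rate")
  check_prob(icc, "icc")
  stopifnot(batch_shift_sd >= 0, batch_scale_sd >= 0, noise_sd >= 0,
            adiposity_noise_sd >= 0)
  if (!length(lod_quantile) %in% c(1L, as.integer(n_features))) {
    stop("`lod_quantile` must be a scalar or one value per feature")
  }
  for (f in names(intake_params)) {
    check_prob(intake_params[[f]]$p_zero, paste0("intake_params$", f, "$p_zero"),
               upper_open = FALSE)
  }
  if (length(true_effects)) {
    if (!all(names(true_effects) %in% .foods)) {
      stop("names of `true_effects` must be foods: ", paste(.foods, collapse = ", "))
    }
    idx <- unlist(lapply(true_effects, function(d) d$feature))
    if (any(idx < 1 | idx > n_features)) stop("true-effect feature index out of range")
    if (anyDuplicated(idx)) {
      stop("conflicting feature index assignments: a feature may carry at most one planted food effect")
    }
  }
  if (length(adiposity_effects)) {
    if (!all(names(adiposity_effects) %in% .outcomes)) {
      stop("names of `adiposity_effects` must be outcomes: ",
           paste(.outcomes, collapse = ", "))
    }
    idx <- unlist(lapply(adiposity_effects, function(d) d$feature))
    if (any(idx < 1 | idx > n_features)) stop("adiposity-effect feature index out of range")
  }
  if (intake_correlation > 0 && n_participants < 10) {
    stop("n_participants < 10 is too small for copula correlation calibration")
  }
  structure(list(
    n_participants = as.integer(n_participants), design = design,
    n_features = as.integer(n_features), n_batches = as.integer(n_batches),
    true_effects = true_effects, intake_params = intake_params,
    intake_correlation = intake_correlation, lod_quantile = lod_quantile,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    adiposity_effects = adiposity_effects,
    covariate_missing_rate = covariate_missing_rate,
    adiposity_shared_sd = adiposity_shared_sd,
    noise_sd = noise_sd, icc = icc, adiposity_noise_sd = adiposity_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Quantile function of the zero-inflated log-normal intake mixture.
q_ziln <- function(u, p_zero, meanlog, sdlog) {
  ifelse(u < p_zero, 0, qlnorm(pmax(0, (u - p_zero) / (1 - p_zero)),
                               meanlog = meanlog, sdlog = sdlog))
}

#' Closed-form quantile of a zero-inflated log-normal intake
#'
#' @param p probability in (0, 1).
#' @param p_zero,meanlog,sdlog mixture parameters.
#' @return the `p`-quantile of the mixture (0 for `p <= p_zero`).
#' @export
ziln_quantile <- function(p, p_zero, meanlog, sdlog) {
  stopifnot(all(p > 0), all(p < 1))
  q_ziln(p, p_zero, meanlog, sdlog)
}

# Calibrate the latent Gaussian-copula correlation so that the *raw-scale*
# Pearson correlation of the transformed SSB/AS intakes hits the target.
# Uses common random numbers (a fixed internal stream, independent of the
# user's seed) so the mapping rho_latent -> r_raw is smooth and monotone.
# The root is deterministic in (target, margins), so it is memoised.
.copula_cache <- new.env(parent = emptyenv())

calibrate_copula <- function(target, ssb, as_par, n_cal = 1e5) {
  if (target <= 0) return(max(0, target))
  key <- paste(format(c(target, unlist(ssb), unlist(as_par), n_cal),
                      digits = 15), collapse = "|")
  hit <- .copula_cache[[key]]
  if (!is.null(hit)) return(hit)
  z <- with_seed(761543L, matrix(rnorm(2 * n_cal), ncol = 2))
  r_of <- function(rho) {
    z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    x <- q_ziln(pnorm(z[, 1]), ssb$p_zero, ssb$meanlog, ssb$sdlog)
    y <- q_ziln(pnorm(z2), as_par$p_zero, as_par$meanlog, as_par$sdlog)
    cor(x, y) - target
  }
  rho <- if (r_of(0.999) < 0) 0.999 else uniroot(r_of, c(0, 0.999), tol = 1e-4)$root
  .copula_cache[[key]] <- rho
  rho
}

#' Generate a synthetic cohort of dietary intakes and covariates
#'
#' Draws one row per sample occasion (two per participant for the children
#' design, one otherwise). Intakes (g/d) are zero-inflated log-normal; SSB
#' and AS are coupled by a Gaussian copula whose latent correlation is
#' calibrated so that the raw-scale Pearson correlation converges to
#' `cfg$intake_correlation`. Total sweetened beverages (`sb`) is the sum of
#' `lncsb` and `ssb`. Covariates: age, sex, total energy intake, physical
#' activity (MET-h/wk), smoking and alcohol status (never/former/current),
#' birthweight; the plasma design additionally carries the number of dietary
#' assessments and the assessment-to-draw time gap (years). Cells of the four
#' imputable covariates are masked at `cfg$covariate_missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return a `data.frame` of class `cohort_table`, with attribute `"design"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dd <- .design_defaults[[cfg$design]]
  n_p <- cfg$n_participants
  occ <- if (cfg$design == "children_repeated") 2L else 1L
  n <- n_p * occ
  with_seed(derive_seed(cfg$seed, "cohort"), {
    pid <- sprintf("P%04d", rep(seq_len(n_p), each = occ))
    occasion <- rep(seq_len(occ), times = n_p)
    sample_id <- sprintf("%s_T%d", pid, occasion)

    rho <- calibrate_copula(cfg$intake_correlation,
                            cfg$intake_params$ssb, cfg$intake_params$as)
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ip <- cfg$intake_params
    ssb <- q_ziln(pnorm(z1), ip$ssb$p_zero, ip$ssb$meanlog, ip$ssb$sdlog)
    as_int <- q_ziln(pnorm(z2), ip$as$p_zero, ip$as$meanlog, ip$as$sdlog)
    lncsb <- q_ziln(runif(n), ip$lncsb$p_zero, ip$lncsb$meanlog, ip$lncsb$sdlog)

    age0 <- rnorm(n_p, dd$age, 0.3)
    age <- age0[rep(seq_len(n_p), each = occ)] + (occasion - 1)
    sex <- factor(rep(sample(c("female", "male"), n_p, replace = TRUE), each = occ),
                  levels = c("female", "male"))
    energy <- exp(rnorm(n, log(dd$energy), 0.18))
    met_hours <- q_ziln(runif(n), 0.05, log(32), 0.8)
    smoking <- factor(rep(sample(c("never", "former", "current"), n_p,
                                 replace = TRUE, prob = c(0.73, 0.11, 0.16)),
                          each = occ), levels = c("current", "former", "never"))
    alcohol <- factor(rep(sample(c("never", "former", "current"), n_p,
                                 replace = TRUE, prob = c(0.13, 0.16, 0.71)),
                          each = occ), levels = c("current", "former", "never"))
    birthweight <- rep(rnorm(n_p, 3400, 450), each = occ)
    anthro_time_diff <- round(rnorm(n, 0, 10))

    cohort <- data.frame(
      sample_id = sample_id, participant_id = pid, occasion = occasion,
      age = age, sex = sex, energy = energy, met_hours = met_hours,
      smoking = smoking, alcohol = alcohol, birthweight = birthweight,
      anthro_time_diff = anthro_time_diff,
      lncsb = lncsb, ssb = ssb, sb = lncsb + ssb, as = as_int,
      stringsAsFactors = FALSE
    )
    if (cfg$design == "adult_plasma") {
      cohort$n_assessments <- sample(3:6, n, replace = TRUE,
                                     prob = c(0.25, 0.35, 0.25, 0.15))
      cohort$time_gap <- round(runif(n, 0.5, 5), 2)
    }
    if (cfg$covariate_missing_rate > 0) {
      for (v in c("birthweight", "met_hours", "alcohol", "smoking")) {
        miss <- runif(n) < cfg$covariate_missing_rate
        cohort[[v]][miss] <- NA
      }
    }
    rownames(cohort) <- cohort$sample_id
    structure(cohort, design = cfg$design, class = c("cohort_table", "data.frame"))
  })
}

#' Generate a synthetic metabolome feature matrix with ground truth
#'
#' Log intensities are built as `baseline + planted intake signal +
#' small age/sex terms (+ participant random intercept for the children
#' design) + Gaussian noise`, then per-(batch, feature) additive location
#' shifts and multiplicative scales are applied on the log scale and the
#' matrix is exponentiated, so all intensities are strictly positive.
#' Features carrying a planted effect have standardized-log intensity
#' `beta * intake(g/d)` plus nuisance terms; all other features are
#' independent of intake.
#'
#' @param cfg a [sim_config()].
#' @param cohort the matching [generate_cohort()] output.
#' @return a list with elements `fm` (a [feature_matrix()], stage `"raw"`,
#'   no missing cells) and `truth` (a `truth_table`: per-food and
#'   per-outcome data frames of feature ids and coefficients).
#' @export
generate_metabolome <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "sim_config"), inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  p <- cfg$n_features
  feature_ids <- sprintf("M%04d", seq_len(p))
  with_seed(derive_seed(cfg$seed, "metabolome"), {
    mu <- rnorm(p, 12, 1)
    b_age <- rnorm(p, 0, 0.05)
    b_sex <- rnorm(p, 0, 0.05)
    L <- matrix(rnorm(n * p, 0, cfg$noise_sd), n, p)
    if (cfg$design == "children_repeated" && cfg$icc > 0 && cfg$noise_sd > 0) {
      sd_u <- cfg$noise_sd * sqrt(cfg$icc / (1 - cfg$icc))
      pid <- factor(cohort$participant_id)
      u <- matrix(rnorm(nlevels(pid) * p, 0, sd_u), nlevels(pid), p)
      L <- L + u[as.integer(pid), , drop = FALSE]
    }
    age_c <- cohort$age - mean(cohort$age)
    sex_num <- as.numeric(cohort$sex == "male")
    L <- L + outer(age_c, b_age) + outer(sex_num, b_sex)
    for (food in names(cfg$true_effects)) {
      eff <- cfg$true_effects[[food]]
      for (i in seq_len(nrow(eff))) {
        L[, eff$feature[i]] <- L[, eff$feature[i]] + eff$beta[i] * cohort[[food]]
      }
    }
    L <- sweep(L, 2, mu, `+`)
    batch <- factor(sprintf("B%d", sample(rep_len(seq_len(cfg$n_batches), n))))
    if (cfg$batch_shift_sd > 0 || cfg$batch_scale_sd > 0) {
      shift <- matrix(rnorm(cfg$n_batches * p, 0, cfg$batch_shift_sd), cfg$n_batches, p)
      scale_ <- matrix(exp(rnorm(cfg$n_batches * p, 0, cfg$batch_scale_sd)),
                       cfg$n_batches, p)
      bi <- as.integer(batch)
      L <- sweep(L, 2, mu) * scale_[bi, , drop = FALSE] +
        shift[bi, , drop = FALSE] + rep(mu, each = n)
    }
    values <- exp(L)
    dimnames(values) <- list(cohort$sample_id, feature_ids)
    fm <- feature_matrix(values, batch = batch, stage = "raw")
    truth <- structure(list(
      foods = lapply(cfg$true_effects, function(d) {
        data.frame(feature = feature_ids[d$feature], beta = d$beta,
                   stringsAsFactors = FALSE)
      }),
      outcomes = lapply(cfg$adiposity_effects, function(d) {
        data.frame(feature = feature_ids[d$feature], coef = d$coef,
                   stringsAsFactors = FALSE)
      })
    ), class = "truth_table")
    list(fm = fm, truth = truth)
  })
}

#' Inject left-censored (detection-limit) missingness
#'
#' Within each feature, the `floor(q * n)` smallest values are masked, where
#' `q` is that feature's `lod_quantile`. Censoring is therefore strictly
#' left-tail: every masked value is at most every observed value of the same
#' feature, and the per-feature missing fraction is within `1/n` of `q`.
#'
#' @param fm a complete (no missing cells) [feature_matrix()].
#' @param cfg a [sim_config()]; `cfg$lod_quantile` may be a scalar or one
#'   value per feature, each in \[0, 1).
#' @return the feature matrix with `NA` cells marking censored values.
#' @export
inject_missingness <- function(fm, cfg) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (anyNA(fm$values)) stop("`fm` must have no missing cells before censoring")
  q <- if (inherits(cfg, "sim_config")) cfg$lod_quantile else cfg
  if (any(q >= 1)) stop("`lod_quantile` must be < 1")
  check_prob(q, "lod_quantile")
  n <- nrow(fm$values)
  q <- rep_len(q, ncol(fm$values))
  for (j in seq_len(ncol(fm$values))) {
    k <- floor(q[j] * n)
    if (k > 0) {
      ord <- order(fm$values[, j])[seq_len(k)]
      fm$values[ord, j] <- NA
    }
  }
  fm
}

#' Append synthetic adiposity outcomes to a cohort
#'
#' Each of BMI, body-fat percentage and waist circumference is generated as
#' `intercept + age/sex/energy terms + sum(coef * standardized-log feature)
#' + noise`, with a participant random intercept in the children design.
#' Planted metabolite effects come from `cfg$adiposity_effects`, expressed
#' per SD of standardized-log intensity.
#'
#' @param cohort a [generate_cohort()] output.
#' @param fm the complete (pre-censoring) [feature_matrix()].
#' @param cfg a [sim_config()].
#' @return the cohort with columns `bmi`, `bf_pct`, `wc` appended.
#' @export
generate_adiposity <- function(cohort, fm, cfg) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(fm, "feature_matrix"),
            inherits(cfg, "sim_config"))
  if (anyNA(fm$values)) stop("adiposity generation needs the pre-censoring matrix")
  dd <- .design_defaults[[cfg$design]]
  n <- nrow(cohort)
  L <- log(fm$values)
  Z <- scale(L)
  base <- c(bmi = dd$bmi, bf_pct = dd$bf, wc = dd$wc)
  scale_out <- c(bmi = 1, bf_pct = 2, wc = 4)
  with_seed(derive_seed(cfg$seed, "adiposity"), {
    u <- if (cfg$design == "children_repeated") {
      pid <- factor(cohort$participant_id)
      rnorm(nlevels(pid), 0, 0.5)[as.integer(pid)]
    } else rep(0, n)
    shared <- rnorm(n, 0, cfg$adiposity_shared_sd %||% 0.45)
    for (out in .outcomes) {
      y <- base[[out]] +
        0.2 * scale_out[[out]] * (cohort$age - mean(cohort$age)) +
        0.3 * scale_out[[out]] * as.numeric(cohort$sex == "male") +
        0.2 * scale_out[[out]] * scale(log(cohort$energy))[, 1] +
        scale_out[[out]] * (u + shared) +
        rnorm(n, 0, cfg$adiposity_noise_sd * scale_out[[out]] / 2)
      eff <- cfg$adiposity_effects[[out]]
      if (!is.null(eff)) {
        if (any(eff$feature > ncol(Z))) {
          stop("adiposity effect references a feature absent from the matrix")
        }
        for (i in seq_len(nrow(eff))) {
          y <- y + eff$coef[i] * Z[, eff$feature[i]]
        }
      }
      cohort[[out]] <- as.numeric(y)
    }
    cohort
  })
}
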