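# Preprocessing: consumer-conditional missingness filtering, three
# imputation variants for detection-limit missingness, log-standardization,
# regression-based batch correction, and Gower-KNN covariate imputation.

#' Filter features by missingness among consumers
#'
#' A feature is evaluated separately for each food group: it enters that
#' food's analysis set only if its missing fraction among the food's
#' consumers is at most `threshold` (the rule is a strict ">": exactly 30%
#' missing is retained at the default threshold). The returned matrix keeps
#' every feature retained for at least one food; the per-food retained lists
#' record which features each food's downstream analysis may use.
#'
#' @param fm a [feature_matrix()] at stage `"raw"`.
#' @param consumers named list `food -> character vector of sample ids` (the
#'   food's consumers); see [consumers_of()].
#' @param threshold maximum tolerated missing fraction (default 0.30).
#' @return a list of class `filter_result`: `fm` (stage `"filtered"`),
#'   `retained` (per-food feature-id lists) and `dropped` (features retained
#'   for no food).
#' @export
filter_missing <- function(fm, consumers, threshold = 0.30) {
  require_stage(fm, "raw", "filter_missing")
  stopifnot(is.list(consumers), length(consumers) >= 1, threshold > 0, threshold < 1)
  retained <- list()
  for (food in names(consumers)) {
    ids <- consumers[[food]]
    if (length(ids) == 0) stop(sprintf("no consumers for food \"%s\"", food))
    if (!all(ids %in% rownames(fm$values))) {
      stop(sprintf("unknown sample ids in consumers of \"%s\"", food))
    }
    frac <- colMeans(is.na(fm$values[ids, , drop = FALSE]))
    retained[[food]] <- colnames(fm$values)[frac <= threshold]
  }
  keep <- sort(unique(unlist(retained)))
  dropped <- setdiff(colnames(fm$values), keep)
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$stage <- "filtered"
  structure(list(fm = fm, retained = retained, dropped = dropped),
            class = "filter_result")
}

#' Identify consumers of each food group
#'
#' @param cohort a `cohort_table`.
#' @param foods food column names (default the four intake exposures).
#' @return named list of sample-id vectors, one per food (intake > 0).
#' @export
consumers_of <- function(cohort, foods = c("lncsb", "ssb", "sb", "as")) {
  setNames(lapply(foods, function(f) cohort$sample_id[cohort[[f]] > 0]), foods)
}

#' Half-minimum imputation within analytical batches
#'
#' Each missing cell is replaced by half of the minimum observed value of
#' that feature within the sample's batch — the standard plug-in for
#' intensities assumed missing because they fell below the detection limit.
#'
#' @param fm a [feature_matrix()] at stage `"raw"`, `"filtered"` or
#'   `"imputed"`.
#' @return the matrix at stage `"imputed"`, with no missing cells. Observed
#'   cells are never altered. A (feature, batch) pair with no observed value
#'   is an error listing the offending pairs.
#' @export
impute_half_min <- function(fm) {
  require_stage(fm, c("raw", "filtered"), "impute_half_min")
  bad <- character()
  for (b in levels(fm$batch)) {
    rows <- fm$batch == b
    block <- fm$values[rows, , drop = FALSE]
    nmiss <- colSums(is.na(block))
    for (j in which(nmiss > 0)) {
      obs <- block[!is.na(block[, j]), j]
      if (length(obs) == 0) {
        bad <- c(bad, sprintf("(%s, %s)", colnames(block)[j], b))
      } else {
        block[is.na(block[, j]), j] <- min(obs) / 2
      }
    }
    fm$values[rows, ] <- block
  }
  if (length(bad)) {
    stop("fully missing (feature, batch) pairs: ", paste(bad, collapse = ", "))
  }
  fm$stage <- "imputed"
  fm
}

#' Censored-quantile (QRILC-style) imputation
#'
#' Treats each feature's missingness as left censoring on the log scale: the
#' observed order statistics are regressed on their standard-normal
#' plotting-position quantiles (offset by the known number of censored
#' values), giving a mean/SD fit of the underlying Gaussian; missing cells
#' are then drawn from the truncated left tail below the censoring point.
#' Imputed values therefore fall at or below the feature's observed minimum
#' in expectation.
#'
#' @param fm a [feature_matrix()] at stage `"raw"` or `"filtered"`.
#' @param seed RNG seed for the truncated-tail draws.
#' @return the matrix at stage `"imputed"`; observed cells are untouched.
#'   Features with (near-)constant observed values fall back to half-minimum
#'   with a warning.
#' @export
impute_censored_quantile <- function(fm, seed = 1) {
  require_stage(fm, c("raw", "filtered"), "impute_censored_quantile")
  vals <- fm$values
  n <- nrow(vals)
  fallback <- character()
  with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      miss <- is.na(vals[, j])
      m <- sum(miss)
      if (m == 0) next
      obs <- log(vals[!miss, j])
      if (length(obs) < 3 || sd(obs) < 1e-12) {
        fallback <- c(fallback, colnames(vals)[j])
        vals[miss, j] <- min(exp(obs)) / 2
        next
      }
      pp <- (m + seq_along(obs) - 0.375) / (n + 0.25)
      fit <- lm(sort(obs) ~ qnorm(pp))
      mu <- coef(fit)[1]
      sigma <- coef(fit)[2]
      if (!is.finite(sigma) || sigma <= 0) {
        fallback <- c(fallback, colnames(vals)[j])
        vals[miss, j] <- min(exp(obs)) / 2
        next
      }
      u <- runif(m, 0, m / n)
      vals[miss, j] <- exp(mu + sigma * qnorm(u))
    }
  })
  if (length(fallback)) {
    warning("constant observed values; half-minimum fallback for: ",
            paste(fallback, collapse = ", "))
  }
  fm$values <- vals
  fm$stage <- "imputed"
  fm
}

#' Iterative random-forest imputation
#'
#' Chained random-forest imputation on the log scale: missing cells are
#' initialised at the feature mean, then each incomplete feature is
#' regressed on all others and its missing cells replaced by the forest
#' predictions, sweeping until the largest standardized change falls below
#' `tol` or `max_iter` sweeps have run (the last iterate is returned with a
#' warning if the tolerance was not reached).
#'
#' @param fm a [feature_matrix()] at stage `"raw"` or `"filtered"`.
#' @param seed RNG seed (forest fits and sweep order).
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence tolerance on the standardized change.
#' @param num_trees trees per forest.
#' @return the matrix at stage `"imputed"`, attribute `"converged"`.
#' @export
impute_forest <- function(fm, seed = 1, max_iter = 10, tol = 1e-3, num_trees = 100) {
  require_stage(fm, c("raw", "filtered"), "impute_forest")
  L <- log(fm$values)
  miss <- is.na(L)
  targets <- which(colSums(miss) > 0)
  if (length(targets) == 0) {
    fm$stage <- "imputed"
    return(fm)
  }
  for (j in targets) L[miss[, j], j] <- mean(L[!miss[, j], j])
  converged <- FALSE
  with_seed(seed, {
    ord <- targets[order(colSums(miss)[targets])]
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in ord) {
        d <- data.frame(.y = L[, j], L[, -j, drop = FALSE], check.names = TRUE)
        obs <- !miss[, j]
        fit <- ranger::ranger(.y ~ ., data = d[obs, , drop = FALSE],
                              num.trees = num_trees, num.threads = 1,
                              seed = sample.int(1e6, 1))
        pred <- predict(fit, d[!obs, , drop = FALSE], num.threads = 1)$predictions
        delta <- max(delta, max(abs(pred - L[!obs, j])) / max(sd(L[obs, j]), 1e-8))
        L[!obs, j] <- pred
      }
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged) warning("random-forest imputation did not converge in ",
                          max_iter, " sweeps; returning last iterate")
  fm$values <- exp(L)
  fm$stage <- "imputed"
  attr(fm, "converged") <- converged
  fm
}

#' Natural-log transform and standardize features
#'
#' Per feature: `x -> ln x`, then centred and scaled to mean zero and unit
#' variance using the population-SD convention (`sd * sqrt((n-1)/n)`), so
#' toy examples are exact. Zero-variance features cannot be standardized and
#' are dropped with a warning. The log-scale centres and scales used are
#' stored as attributes `"log_center"` / `"log_scale"` so planted effects can
#' be mapped onto the analysis scale.
#'
#' @param fm a [feature_matrix()] at stage `"imputed"` (or a complete raw
#'   matrix).
#' @return the matrix at stage `"standardized"`.
#' @export
log_standardize <- function(fm) {
  require_stage(fm, c("raw", "filtered", "imputed"), "log_standardize")
  if (anyNA(fm$values)) stop("log_standardize requires a complete matrix; impute first")
  L <- log(fm$values)
  n <- nrow(L)
  ctr <- colMeans(L)
  scl <- apply(L, 2, sd) * sqrt((n - 1) / n)
  zero <- scl < 1e-12
  if (any(zero)) {
    warning("dropping zero-variance features: ",
            paste(colnames(L)[zero], collapse = ", "))
    L <- L[, !zero, drop = FALSE]
    ctr <- ctr[!zero]
    scl <- scl[!zero]
  }
  fm$values <- sweep(sweep(L, 2, ctr), 2, scl, `/`)
  fm$stage <- "standardized"
  attr(fm, "log_center") <- ctr
  attr(fm, "log_scale") <- scl
  fm
}

#' Remove analytical batch effects (location/scale regression)
#'
#' Per feature, batch means are estimated by regression on batch indicators
#' and subtracted, and each batch's residual spread is rescaled to the
#' pooled residual SD. After correction the per-feature batch means are
#' exactly zero and the per-batch SDs are equal, so a one-way ANOVA of
#' feature on batch sits at its null expectation. The transform is affine
#' and increasing within each batch, so cross-sample ordering within a batch
#' is preserved.
#'
#' @param fm a [feature_matrix()] at stage `"standardized"` with at least 2
#'   samples per batch.
#' @return the matrix at stage `"corrected"`.
#' @export
correct_batch <- function(fm) {
  require_stage(fm, "standardized", "correct_batch")
  tab <- table(fm$batch)
  if (any(tab < 2)) {
    stop("batches with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  bi <- as.integer(fm$batch)
  nb <- nlevels(fm$batch)
  V <- fm$values
  n <- nrow(V)
  for (j in seq_len(ncol(V))) {
    x <- V[, j]
    mb <- tapply(x, bi, mean)
    r <- x - mb[bi]
    sb <- sqrt(tapply(r^2, bi, mean))
    s_pool <- sqrt(mean(r^2))
    sb[sb < 1e-12] <- s_pool
    if (s_pool < 1e-12) s_pool <- 1
    V[, j] <- r / sb[bi] * s_pool
  }
  fm$values <- V
  fm$stage <- "corrected"
  fm
}

#' KNN imputation of phenotype covariates
#'
#' Imputes birthweight, physical activity, alcohol and smoking status from
#' the `k` nearest participants under a Gower distance over the mixed-type
#' predictor set (sex, age, BMI, energy intake, birthweight, physical
#' activity, alcohol, smoking), computed on non-missing covariates.
#' Continuous targets take the neighbour mean; categorical targets the
#' neighbour majority, ties broken alphabetically.
#'
#' @param cohort a `cohort_table`.
#' @param k number of neighbours (default 10).
#' @param targets covariates to impute.
#' @return the cohort with no missing values among the targets.
#' @export
knn_impute_covariates <- function(cohort, k = 10,
                                  targets = c("birthweight", "met_hours",
                                              "alcohol", "smoking")) {
  check_count(k, "k")
  if (k > nrow(cohort) - 1) stop("`k` must be at most n - 1")
  predictors <- intersect(c("sex", "age", "bmi", "energy", "birthweight",
                            "met_hours", "alcohol", "smoking"), names(cohort))
  pf <- as.data.frame(cohort)[, predictors, drop = FALSE]
  if (any(rowSums(!is.na(pf)) == 0)) {
    stop("rows with all predictors missing cannot be imputed: ",
         paste(cohort$sample_id[rowSums(!is.na(pf)) == 0], collapse = ", "))
  }
  targets <- intersect(targets, names(cohort))
  if (!anyNA(cohort[, targets])) return(cohort)
  D <- as.matrix(cluster::daisy(pf, metric = "gower", warnBin = FALSE,
                                warnAsym = FALSE, warnConst = FALSE))
  diag(D) <- Inf
  for (v in targets) {
    miss0 <- is.na(cohort[[v]])
    for (i in which(miss0)) {
      d <- D[i, ]
      d[miss0] <- Inf
      d[!is.finite(d)] <- Inf
      nb <- order(d)[seq_len(k)]
      vals <- cohort[[v]][nb]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) stop("no usable neighbours for ", v)
      if (is.numeric(vals)) {
        cohort[[v]][i] <- mean(vals)
      } else {
        tab <- table(as.character(vals))
        win <- names(tab)[tab == max(tab)]
        cohort[[v]][i] <- sort(win)[1]
      }
    }
  }
  cohort
}
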