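# Joint adiposity models: VIF-based collinearity pruning, a
# correlation-adjusted significance threshold for the three outcomes, joint
# linear / random-intercept fits, and an adaptive elastic-net sensitivity
# analysis.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from regressing predictor `j` on
#' all other predictors (intercept included). Computed from the inverse of
#' the predictor correlation matrix, with a per-column regression fallback
#' when the matrix is singular; perfectly collinear predictors are reported
#' as `Inf`.
#'
#' @param design numeric matrix or data frame of predictors (n x p, p >= 2,
#'   n > p). Factors are expanded to treatment-coded indicators.
#' @return named numeric vector of VIFs, one per column of the expanded
#'   design.
#' @export
compute_vif <- function(design) {
  X <- if (is.data.frame(design)) {
    model.matrix(~ ., data = design)[, -1, drop = FALSE]
  } else {
    as.matrix(design)
  }
  if (ncol(X) < 2) stop("VIF needs at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop("VIF needs n > p")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  R <- suppressWarnings(cor(X))
  vif <- tryCatch({
    v <- diag(solve(R))
    if (any(!is.finite(v)) || any(v < 0)) stop("fallback")
    v
  }, error = function(e) {
    vapply(seq_len(ncol(X)), function(j) {
      r2 <- suppressWarnings(summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  })
  setNames(as.numeric(vif), colnames(X))
}

#' Iterative VIF pruning of metabolite predictors
#'
#' Repeatedly computes VIFs over the full design (metabolites plus
#' covariates), removes the metabolite with the highest VIF whenever that
#' VIF exceeds `threshold` (ties, including ties at `Inf`, are broken by
#' removing the alphabetically last feature id), and recomputes after every
#' single removal. Covariates are part of the design but exempt from
#' removal.
#'
#' @param metabolites numeric matrix of metabolite predictors (named
#'   columns).
#' @param covariates optional data frame of covariates kept in the design.
#' @param threshold VIF threshold (default 10).
#' @return a list: `kept` (surviving metabolite ids) and `removal_trace`
#'   (data frame of `(feature, vif)` in removal order).
#' @export
prune_vif <- function(metabolites, covariates = NULL, threshold = 10) {
  M <- as.matrix(metabolites)
  if (is.null(colnames(M))) colnames(M) <- sprintf("V%d", seq_len(ncol(M)))
  cov_mm <- if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  } else NULL
  trace <- data.frame(feature = character(), vif = numeric(),
                      stringsAsFactors = FALSE)
  repeat {
    if (ncol(M) == 0) break
    X <- if (is.null(cov_mm)) M else cbind(M, cov_mm)
    if (ncol(X) < 2) break
    vifs <- compute_vif(X)[colnames(M)]
    mx <- max(vifs)
    if (!(mx > threshold)) break
    tied <- names(vifs)[vifs == mx]
    victim <- sort(tied)[length(tied)] # alphabetically last of the tied
    trace <- rbind(trace, data.frame(feature = victim, vif = mx,
                                     stringsAsFactors = FALSE))
    M <- M[, setdiff(colnames(M), victim), drop = FALSE]
  }
  list(kept = colnames(M), removal_trace = trace)
}

#' Correlation-adjusted significance threshold for correlated outcomes
#'
#' Sankoh-style modified Bonferroni adjustment for `k` correlated endpoints:
#' `alpha_adj = 1 - (1 - alpha)^(1 / k^(1 - rbar))`, where `rbar` is the
#' mean pairwise Pearson correlation among the outcomes (negative
#' correlations are truncated to zero with a warning). Perfectly correlated
#' outcomes need no adjustment (`alpha_adj = alpha`); independent outcomes
#' recover the Sidak correction.
#'
#' @param outcomes numeric matrix of outcome measures (n x k, k >= 2); rows
#'   with missing values are dropped.
#' @param alpha nominal level (default 0.05).
#' @return the adjusted threshold, in `(0, alpha]`.
#' @export
adjusted_alpha <- function(outcomes, alpha = 0.05) {
  outcomes <- as.matrix(outcomes)
  outcomes <- outcomes[complete.cases(outcomes), , drop = FALSE]
  k <- ncol(outcomes)
  if (k < 2) stop("need at least 2 outcome columns")
  R <- cor(outcomes)
  rbar <- mean(R[upper.tri(R)])
  if (rbar < 0) {
    if (rbar < -1e-8) warning("negative mean outcome correlation truncated to 0")
    rbar <- 0
  }
  sankoh_alpha(k, min(rbar, 1), alpha)
}

#' @rdname adjusted_alpha
#' @param k number of endpoints.
#' @param rbar mean pairwise Pearson correlation among the endpoints, in
#'   \[0, 1\].
#' @export
sankoh_alpha <- function(k, rbar, alpha = 0.05) {
  stopifnot(k >= 2, rbar >= 0, rbar <= 1, alpha > 0, alpha < 1)
  a <- 1 - (1 - alpha)^(1 / k^(1 - rbar))
  min(max(a, .Machine$double.eps), alpha)
}

#' Joint adiposity model for one outcome
#'
#' Applies [prune_vif()] to the metabolite set, then fits one joint model of
#' the outcome on the surviving metabolites plus covariates — a
#' random-intercept mixed model for the children design, OLS otherwise —
#' and reports each metabolite's coefficient with Wald 95% CI and p-value,
#' flagged significant at `alpha_adjusted`.
#'
#' @param outcome numeric outcome vector (BMI/BMI-SDS, body-fat %, or WC).
#' @param metabolites numeric matrix of food-related metabolite predictors.
#' @param covariates data frame of adjustment covariates (complete cases;
#'   impute upstream).
#' @param design sampling design (children gets the random intercept).
#' @param participant_id required for the children design.
#' @param outcome_name label carried into the report.
#' @param alpha_adjusted significance threshold (see [adjusted_alpha()]).
#' @param vif_threshold VIF pruning threshold (default 10).
#' @return an object of class `adiposity_report`.
#' @export
fit_adiposity <- function(outcome, metabolites, covariates, design,
                          participant_id = NULL, outcome_name = "outcome",
                          alpha_adjusted = 0.05, vif_threshold = 10) {
  design <- match.arg(design, .designs)
  M <- as.matrix(metabolites)
  if (anyNA(outcome) || anyNA(M) || anyNA(covariates)) {
    stop("outcome, metabolites and covariates must be complete; impute upstream")
  }
  pr <- if (ncol(M) >= 2) prune_vif(M, covariates, vif_threshold) else {
    list(kept = colnames(M),
         removal_trace = data.frame(feature = character(), vif = numeric()))
  }
  keep <- pr$kept
  if (length(keep) == 0) stop("VIF pruning removed every metabolite")
  M <- M[, keep, drop = FALSE]
  df <- data.frame(.y = outcome, as.data.frame(covariates), M,
                   check.names = FALSE, stringsAsFactors = FALSE)
  p_tot <- ncol(M) + ncol(model.matrix(~ ., data = as.data.frame(covariates)))
  if (nrow(df) <= p_tot) {
    stop("n <= number of predictors after pruning; tighten the VIF threshold ",
         "or use the regularized sensitivity path")
  }
  rhs <- paste(sprintf("`%s`", setdiff(names(df), ".y")), collapse = " + ")
  mixed <- design == "children_repeated"
  if (mixed) {
    if (is.null(participant_id)) stop("children design requires `participant_id`")
    df$participant_id <- participant_id
    fit <- lme4::lmer(as.formula(paste(".y ~", rhs, "+ (1 | participant_id)")),
                      data = df, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
  } else {
    fit <- lm(as.formula(paste(".y ~", rhs)), data = df)
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
  }
  names(cf) <- gsub("`", "", names(cf))
  names(se) <- names(cf)
  ids <- keep
  zq <- qnorm(0.975)
  res <- data.frame(
    feature = keep, beta = unname(cf[ids]),
    ci_low = unname(cf[ids] - zq * se[ids]),
    ci_high = unname(cf[ids] + zq * se[ids]),
    p = unname(2 * pnorm(-abs(cf[ids] / se[ids]))),
    stringsAsFactors = FALSE
  )
  res$significant <- res$p < alpha_adjusted
  structure(list(outcome = outcome_name, retained = res,
                 removal_trace = pr$removal_trace,
                 alpha_adjusted = alpha_adjusted,
                 model_kind = if (mixed) "mixed" else "linear",
                 n = nrow(df), sensitivity = NULL),
            class = "adiposity_report")
}

#' @method print adiposity_report
#' @export
print.adiposity_report <- function(x, ...) {
  cat(sprintf("<adiposity_report> outcome %s (%s model, n = %d)\n",
              x$outcome, x$model_kind, x$n))
  cat(sprintf("  alpha_adjusted = %.4g; %d metabolites retained, %d pruned, %d significant\n",
              x$alpha_adjusted, nrow(x$retained), nrow(x$removal_trace),
              sum(x$retained$significant)))
  invisible(x)
}

#' Adaptive elastic-net sensitivity analysis
#'
#' Confounder-adjusted robustness check for the joint adiposity models: the
#' outcome and each metabolite are first residualized on the covariates,
#' then a ridge stage provides adaptive weights `w_j = 1 / |b_j|^gamma`
#' (coefficients of exactly zero are capped at a large constant), and an
#' elastic-net stage with per-feature penalty weights, tuned by 5-fold
#' cross-validation (one-SE penalty), returns the features with nonzero
#' coefficients.
#'
#' @param outcome numeric outcome vector.
#' @param metabolites numeric metabolite matrix (named columns).
#' @param covariates data frame of confounders.
#' @param seed RNG seed for the cross-validation folds.
#' @param alpha_mix elastic-net mixing parameter of the second stage
#'   (default 0.5).
#' @param gamma adaptive-weight exponent (default 1).
#' @param nfolds cross-validation folds (default 5).
#' @param weight_cap cap for infinite adaptive weights.
#' @return character vector of features with nonzero coefficients.
#' @export
adaptive_enet_sensitivity <- function(outcome, metabolites, covariates, seed = 1,
                                      alpha_mix = 0.5, gamma = 1, nfolds = 5,
                                      weight_cap = 1e6) {
  M <- as.matrix(metabolites)
  if (ncol(M) < 2) stop("need at least 2 metabolites")
  cov_df <- as.data.frame(covariates)
  cov_mm <- model.matrix(~ ., data = cov_df)
  Q <- qr(cov_mm)
  Mr <- qr.resid(Q, M)
  yr <- qr.resid(Q, outcome)
  colnames(Mr) <- colnames(M)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), length(yr)))
    ridge <- glmnet::cv.glmnet(Mr, yr, alpha = 0, foldid = foldid)
    b1 <- abs(as.matrix(coef(ridge, s = "lambda.min"))[-1, 1])
    w <- ifelse(b1 < 1 / weight_cap, weight_cap, 1 / b1^gamma)
    enet <- glmnet::cv.glmnet(Mr, yr, alpha = alpha_mix, penalty.factor = w,
                              foldid = foldid)
    cf <- as.matrix(coef(enet, s = "lambda.1se"))[-1, 1]
    names(cf)[cf != 0]
  })
}
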