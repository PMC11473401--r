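# Covariate-adjusted food-metabolite association models with
# repeated-measures support and Benjamini-Hochberg FDR control.

# Design-locked covariate sets. Children models carry a participant random
# intercept; adolescent models add lifestyle covariates; plasma models
# additionally adjust for the number of dietary assessments and the
# assessment-to-draw time gap.
.covariate_sets <- list(
  children_repeated = c("age", "sex", "energy"),
  adolescent_single = c("age", "sex", "energy", "met_hours", "alcohol", "smoking"),
  adult_plasma = c("age", "sex", "energy", "met_hours", "alcohol", "smoking",
                   "n_assessments", "time_gap")
)

#' Covariate set mandated by a sampling design
#'
#' @param design one of the three sampling designs.
#' @return character vector of covariate column names.
#' @export
covariates_for_design <- function(design) {
  design <- match.arg(design, .designs)
  .covariate_sets[[design]]
}

#' Specify one food-metabolite association model
#'
#' Covariate sets are design-locked: supplying a covariate list that differs
#' from the design's mandated set raises an error.
#'
#' @param response feature id (column of the analysis matrix).
#' @param exposure food intake column (g/d).
#' @param design sampling design; fixes covariates and the random intercept.
#' @param covariates optional explicit covariate set; must equal the
#'   design's set.
#' @param random_intercept logical; defaults to `TRUE` for the children
#'   design only. Requesting a random intercept for a single-occasion design
#'   is an error.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, exposure, design, covariates = NULL,
                       random_intercept = NULL) {
  design <- match.arg(design, .designs)
  mandated <- .covariate_sets[[design]]
  if (!is.null(covariates) && !setequal(covariates, mandated)) {
    stop(sprintf("covariate set for design \"%s\" is locked to {%s}", design,
                 paste(mandated, collapse = ", ")))
  }
  ri <- random_intercept %||% (design == "children_repeated")
  if (ri && design != "children_repeated") {
    stop("a random intercept requires repeated occasions (children design)")
  }
  structure(list(response = response, exposure = exposure, design = design,
                 covariates = mandated, random_intercept = ri),
            class = "model_spec")
}

model_frame <- function(spec, data) {
  cols <- c(spec$response, spec$exposure, spec$covariates,
            if (spec$random_intercept) "participant_id")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) stop("missing model columns: ",
                                 paste(missing_cols, collapse = ", "))
  mf <- data[, cols, drop = FALSE]
  if (anyNA(mf)) {
    bad <- names(mf)[vapply(mf, anyNA, logical(1))]
    stop("missing cells in model columns (impute covariates upstream): ",
         paste(bad, collapse = ", "))
  }
  mf
}

wald_row <- function(spec, beta, se, model_kind, n, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(food = spec$exposure, feature = spec$response, beta = beta,
             ci_low = beta - zq * se, ci_high = beta + zq * se,
             p = 2 * pnorm(-abs(beta / se)), model = model_kind, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a cross-sectional food-metabolite association (OLS)
#'
#' Ordinary least squares of the (standardized-log) metabolite on intake in
#' g/d plus the design's covariates. Categorical covariates are expanded as
#' treatment-coded indicators with the alphabetically first level as
#' reference. The exposure coefficient is reported with a Wald
#' (normal-approximation) 95% CI and two-sided p-value.
#'
#' @param spec a [model_spec()].
#' @param data data frame containing the response, exposure and covariates
#'   (one row per sample; no missing cells in model columns).
#' @return a one-row association data frame
#'   `(food, feature, beta, ci_low, ci_high, p, model, n)`.
#' @export
fit_linear <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  mf <- model_frame(spec, data)
  mf <- droplevels(mf)
  for (v in names(mf)) {
    if (is.factor(mf[[v]])) mf[[v]] <- factor(mf[[v]], levels = sort(levels(mf[[v]])))
    if (is.character(mf[[v]]) && v != "participant_id") mf[[v]] <- factor(mf[[v]])
  }
  rhs <- paste(c(sprintf("`%s`", spec$exposure), sprintf("`%s`", spec$covariates)),
               collapse = " + ")
  form <- as.formula(sprintf("`%s` ~ %s", spec$response, rhs))
  n <- nrow(mf)
  fit <- lm(form, data = mf)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  if (n <= length(coef(fit)) + 2) stop("too few rows for the model size")
  cf <- coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(cf)
  wald_row(spec, cf[[spec$exposure]], se[[spec$exposure]], "linear", n)
}

#' Fit a repeated-measures food-metabolite association (random intercept)
#'
#' Linear mixed-effects model with a participant random intercept, fitted by
#' REML; the exposure fixed effect is reported with a Wald CI and p-value.
#' If the random-intercept variance is estimated on the zero boundary
#' (singular fit), the model falls back to OLS with a warning and
#' `model = "linear_fallback"`.
#'
#' @inheritParams fit_linear
#' @param fallback fall back to OLS on a singular fit (default `TRUE`);
#'   otherwise a singular fit is an error.
#' @return a one-row association data frame; `model` is `"mixed"` plus
#'   attribute `"varcomp"` with the estimated variance components.
#' @export
fit_mixed <- function(spec, data, fallback = TRUE) {
  stopifnot(inherits(spec, "model_spec"), spec$random_intercept)
  mf <- model_frame(spec, data)
  if (max(table(mf$participant_id)) < 2) {
    stop("random intercept requires >= 2 occasions for some participants")
  }
  rhs <- paste(c(sprintf("`%s`", spec$exposure), sprintf("`%s`", spec$covariates)),
               collapse = " + ")
  form <- as.formula(sprintf("`%s` ~ %s + (1 | participant_id)", spec$response, rhs))
  fit <- lme4::lmer(form, data = mf, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    if (!fallback) stop("singular random-intercept fit and fallback disabled")
    warning("random-intercept variance on the zero boundary; falling back to OLS")
    spec_ols <- spec
    spec_ols$random_intercept <- FALSE
    row <- fit_linear(spec_ols, data)
    row$model <- "linear_fallback"
    return(row)
  }
  cf <- lme4::fixef(fit)
  names(cf) <- gsub("`", "", names(cf))
  se <- sqrt(diag(as.matrix(vcov(fit))))
  names(se) <- names(cf)
  row <- wald_row(spec, cf[[spec$exposure]], se[[spec$exposure]], "mixed", nrow(mf))
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(row, "varcomp") <- setNames(vc$vcov, vc$grp)
  row
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with enforced monotonicity, controlling the false
#' discovery rate at the nominal level when the flag threshold `q < 0.05`
#' is used.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# Vectorised OLS over many responses sharing one design matrix; agrees
# with fit_linear() to machine precision.
associate_ols_block <- function(data, Y, food, design) {
  spec <- model_spec(colnames(Y)[1], food, design)
  cols <- c(spec$exposure, spec$covariates)
  mf <- data[, cols, drop = FALSE]
  if (anyNA(mf) || anyNA(Y)) {
    stop("missing cells in model columns (impute covariates upstream)")
  }
  mf <- droplevels(mf)
  for (v in names(mf)) {
    if (is.factor(mf[[v]])) mf[[v]] <- factor(mf[[v]], levels = sort(levels(mf[[v]])))
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  }
  X <- model.matrix(~ ., data = mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient design; aliased columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  }
  n <- nrow(X)
  if (n <= ncol(X) + 2) stop("too few rows for the model size")
  B <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / (n - ncol(X))
  xtx_inv <- chol2inv(qr.R(qx))
  rownames(xtx_inv) <- colnames(xtx_inv) <- colnames(X)[qx$pivot]
  jj <- xtx_inv[spec$exposure, spec$exposure]
  beta <- B[spec$exposure, ]
  se <- sqrt(sigma2 * jj)
  zq <- qnorm(0.975)
  data.frame(food = food, feature = colnames(Y), beta = unname(beta),
             ci_low = unname(beta - zq * se), ci_high = unname(beta + zq * se),
             p = unname(2 * pnorm(-abs(beta / se))), model = "linear", n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association table for a food's consensus metabolites
#'
#' Fits one covariate-adjusted model per feature (mixed for the children
#' design, linear otherwise) and applies BH adjustment within the
#' (food, design) family.
#'
#' @param fm analysis-ready [feature_matrix()] (stage `"corrected"` or
#'   `"standardized"`).
#' @param cohort `cohort_table` with imputed covariates.
#' @param features feature ids to test (e.g. a [consensus()] set).
#' @param food intake column name.
#' @param design sampling design.
#' @return a data frame of class `association_table` with columns
#'   `(food, feature, beta, ci_low, ci_high, p, q, model, n)`.
#' @export
associate <- function(fm, cohort, features, food, design) {
  stopifnot(inherits(fm, "feature_matrix"))
  require_stage(fm, c("standardized", "corrected"), "associate")
  features <- intersect(features, colnames(fm$values))
  data <- cbind(as.data.frame(cohort),
                as.data.frame(fm$values[cohort$sample_id, , drop = FALSE]))
  ri <- design == "children_repeated"
  out <- if (ri || length(features) < 2) {
    rows <- lapply(features, function(f) {
      spec <- model_spec(f, food, design)
      if (spec$random_intercept) fit_mixed(spec, data) else fit_linear(spec, data)
    })
    do.call(rbind, rows)
  } else {
    # one shared design matrix across features: a single QR reproduces
    # fit_linear for every response at once
    associate_ols_block(data, fm$values[cohort$sample_id, features,
                                        drop = FALSE], food, design)
  }
  if (is.null(out)) {
    out <- data.frame(food = character(), feature = character(), beta = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      q = numeric(), model = character(), n = integer())
  } else {
    out$q <- bh_adjust(out$p)
    out <- out[, c("food", "feature", "beta", "ci_low", "ci_high", "p", "q",
                   "model", "n")]
  }
  structure(out, class = c("association_table", "data.frame"))
}
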