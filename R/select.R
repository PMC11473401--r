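# Variable selection: repeated double cross-validation (PLS / random
# forest) with recursive backward elimination, bagged LASSO with
# elbow-point frequency cutoffs, and the >= 2-method consensus rule.

#' Configuration for the variable selectors
#'
#' Defaults follow the published scale of the procedures: 50 repetitions of
#' the double cross-validation scheme (5 outer / 4 inner folds, 20% of
#' variables eliminated per round), 1000 bootstrap LASSO fits tuned by
#' 5-fold cross-validation. The scaled-down profile used by the package's
#' simulation studies overrides these (see the methods vignette).
#'
#' @param method `"rdcv_pls"`, `"rdcv_rf"` or `"lasso_bag"`.
#' @param n_repetitions repetitions of the outer double-CV loop.
#' @param outer_folds,inner_folds fold counts (>= 2).
#' @param drop_fraction fraction of variables eliminated per backward round.
#' @param n_bootstrap bootstrap resamples for the bagged LASSO.
#' @param cv_folds_lasso folds for the per-bootstrap penalty tuning.
#' @param num_trees trees per random forest.
#' @param rf_importance ranger importance mode (`"permutation"` default).
#' @param max_ncomp maximum PLS components tuned in the inner loop.
#' @param lambda_choice `"min"` (CV-minimum penalty, default) or `"1se"`.
#' @param nlambda length of the glmnet penalty path.
#' @param prominence elbow prominence rule, see [detect_elbow()].
#' @param seed RNG seed; fixes the full report.
#' @return an object of class `selector_config`.
#' @export
selector_config <- function(method = c("rdcv_pls", "rdcv_rf", "lasso_bag"),
                            n_repetitions = 50, outer_folds = 5, inner_folds = 4,
                            drop_fraction = 0.2, n_bootstrap = 1000,
                            cv_folds_lasso = 5, num_trees = 500,
                            rf_importance = c("permutation", "impurity"),
                            max_ncomp = 5, lambda_choice = c("min", "1se"),
                            nlambda = 100,
                            prominence = c("relative", "mean_sd"),
                            seed = 1) {
  method <- match.arg(method)
  check_count(n_repetitions, "n_repetitions")
  check_count(outer_folds, "outer_folds", min = 2L)
  check_count(inner_folds, "inner_folds", min = 2L)
  check_count(n_bootstrap, "n_bootstrap")
  check_count(cv_folds_lasso, "cv_folds_lasso", min = 2L)
  check_count(num_trees, "num_trees")
  if (drop_fraction <= 0 || drop_fraction >= 1) stop("`drop_fraction` must be in (0,1)")
  structure(list(method = method, n_repetitions = as.integer(n_repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 drop_fraction = drop_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 cv_folds_lasso = as.integer(cv_folds_lasso),
                 num_trees = as.integer(num_trees),
                 rf_importance = match.arg(rf_importance),
                 max_ncomp = as.integer(max_ncomp),
                 lambda_choice = match.arg(lambda_choice),
                 nlambda = as.integer(nlambda),
                 prominence = match.arg(prominence),
                 seed = as.integer(seed)),
            class = "selector_config")
}

new_selection_report <- function(method, food, ranked, selected, q2 = NA_real_,
                                 counts = NULL, frequency_curve = NULL,
                                 elbow_index = NULL, n_models = NA_integer_) {
  structure(list(method = method, food = food, ranked_features = ranked,
                 selected_set = selected, q2 = q2, counts = counts,
                 frequency_curve = frequency_curve, elbow_index = elbow_index,
                 n_models = n_models),
            class = "selection_report")
}

#' @method print selection_report
#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> method %s%s: %d selected\n", x$method,
              if (!is.null(x$food)) paste0(", food ", x$food) else "",
              length(x$selected_set)))
  if (!is.na(x$q2)) cat(sprintf("  mean outer Q2: %.3f\n", x$q2))
  if (!is.null(x$elbow_index)) cat(sprintf("  elbow cutoff at index %d\n", x$elbow_index))
  if (length(x$selected_set)) {
    cat("  top: ", paste(head(x$selected_set, 8), collapse = ", "), "\n")
  }
  invisible(x)
}

# Inner validation error + importance for one candidate variable set.
# PLS: inner-fold CV RMSEP minimised over 1..max_ncomp components, VIP from
# a full-train refit at the tuned size. RF: a single forest whose OOB error
# plays the inner-validation role (no tuned hyperparameter), importance from
# the same fit.
inner_eval <- function(X, y, vars, cfg) {
  Xv <- X[, vars, drop = FALSE]
  n <- nrow(Xv)
  if (cfg$method == "rdcv_pls") {
    ncmax <- min(cfg$max_ncomp, length(vars), n - 2)
    fold <- sample(rep_len(seq_len(cfg$inner_folds), n))
    sse <- numeric(ncmax)
    for (k in seq_len(cfg$inner_folds)) {
      tr <- fold != k
      if (sum(tr) < 3) next
      fit <- pls_fit(Xv[tr, , drop = FALSE], y[tr], ncmax)
      for (a in seq_len(fit$ncomp)) {
        pr <- predict(fit, Xv[!tr, , drop = FALSE], ncomp = a)
        sse[a] <- sse[a] + sum((y[!tr] - pr)^2)
      }
      if (fit$ncomp < ncmax) sse[(fit$ncomp + 1):ncmax] <- Inf
    }
    best_nc <- which.min(sse)
    full <- pls_fit(Xv, y, best_nc)
    list(error = sqrt(sse[best_nc] / n), importance = pls_vip(full),
         ncomp = best_nc)
  } else {
    d <- data.frame(.y = y, Xv, check.names = FALSE)
    fit <- ranger::ranger(.y ~ ., data = d, num.trees = cfg$num_trees,
                          importance = cfg$rf_importance, num.threads = 1,
                          seed = sample.int(1e6, 1))
    list(error = sqrt(fit$prediction.error),
         importance = fit$variable.importance, ncomp = NA_integer_)
  }
}

refit_predict <- function(X, y, vars, newX, cfg, ncomp) {
  if (cfg$method == "rdcv_pls") {
    fit <- pls_fit(X[, vars, drop = FALSE], y, max(1, ncomp))
    as.numeric(predict(fit, newX[, vars, drop = FALSE]))
  } else {
    d <- data.frame(.y = y, X[, vars, drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(.y ~ ., data = d, num.trees = cfg$num_trees,
                          num.threads = 1, seed = sample.int(1e6, 1))
    nd <- data.frame(newX[, vars, drop = FALSE], check.names = FALSE)
    predict(fit, nd, num.threads = 1)$predictions
  }
}

#' Variable selection by repeated double cross-validation
#'
#' Within each of `n_repetitions` random outer splits, every outer training
#' set undergoes recursive backward elimination: the base learner (PLS tuned
#' over 1-5 components by inner-fold RMSEP, or a random forest validated by
#' its out-of-bag error) is fitted, the `drop_fraction` least important
#' variables (PLS VIP, or forest permutation importance) are removed, and
#' the inner validation error is tracked per model size. The size minimising
#' inner error (ties to the smaller model) defines that model's selection;
#' the final `selected_set` contains variables selected in a majority of the
#' `n_repetitions * outer_folds` models. Mean outer-fold validation R-squared
#' (Q2) of the per-model winners is reported as a fitness check.
#'
#' @param X analysis-ready matrix (samples x features, named columns).
#' @param y intake vector (g/d, untransformed).
#' @param cfg a [selector_config()] with method `"rdcv_pls"` or `"rdcv_rf"`.
#' @param food optional food label carried into the report.
#' @return a `selection_report`.
#' @export
rdcv_select <- function(X, y, cfg, food = NULL) {
  stopifnot(inherits(cfg, "selector_config"))
  if (!cfg$method %in% c("rdcv_pls", "rdcv_rf")) {
    stop("`cfg$method` must be rdcv_pls or rdcv_rf")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  if (sd(y) < 1e-12) stop("`y` is constant")
  if (n < 4 * cfg$outer_folds) stop("n must be at least 4 * outer_folds")
  sel_count <- setNames(numeric(p), colnames(X))
  rank_sum <- setNames(numeric(p), colnames(X))
  models <- list()
  q2s <- c()
  with_seed(cfg$seed, {
    for (rep_i in seq_len(cfg$n_repetitions)) {
      fold <- sample(rep_len(seq_len(cfg$outer_folds), n))
      for (k in seq_len(cfg$outer_folds)) {
        tr <- fold != k
        Xtr <- X[tr, , drop = FALSE]
        ytr <- y[tr]
        vars <- colnames(X)
        hist_vars <- list()
        hist_err <- c()
        hist_ncomp <- c()
        rank_vec <- setNames(rep(NA_real_, p), colnames(X))
        next_rank <- p
        repeat {
          ev <- inner_eval(Xtr, ytr, vars, cfg)
          hist_vars[[length(hist_vars) + 1L]] <- vars
          hist_err <- c(hist_err, ev$error)
          hist_ncomp <- c(hist_ncomp, ev$ncomp)
          if (length(vars) == 1) {
            rank_vec[vars] <- next_rank
            break
          }
          ndrop <- max(1L, floor(length(vars) * cfg$drop_fraction))
          ord <- order(ev$importance, decreasing = FALSE)
          drop_vars <- vars[ord[seq_len(ndrop)]]
          # eliminated earlier => worse (larger) rank; within a round, the
          # least important of the dropped gets the worst rank
          for (v in drop_vars[order(ev$importance[drop_vars])]) {
            rank_vec[v] <- next_rank
            next_rank <- next_rank - 1L
          }
          vars <- setdiff(vars, drop_vars)
        }
        rank_sum <- rank_sum + rank_vec
        models[[length(models) + 1L]] <- list(tr = tr, hist_vars = hist_vars,
                                              hist_err = hist_err,
                                              hist_ncomp = hist_ncomp)
      }
    }
    # the "min" model: the size minimising the MEAN inner validation error
    # across all repetition x outer-segment models (the elimination schedule
    # is deterministic, so rounds align); ties go to the smaller model
    n_rounds <- length(models[[1]]$hist_err)
    err_mat <- matrix(vapply(models, `[[`, numeric(n_rounds), "hist_err"),
                      nrow = n_rounds)
    mean_err <- rowMeans(err_mat)
    best <- max(which(mean_err == min(mean_err)))
    for (m in models) {
      chosen <- m$hist_vars[[best]]
      sel_count[chosen] <- sel_count[chosen] + 1
      pr <- refit_predict(X[m$tr, , drop = FALSE], y[m$tr], chosen,
                          X[!m$tr, , drop = FALSE], cfg,
                          ncomp = m$hist_ncomp[best])
      yte <- y[!m$tr]
      q2s <- c(q2s, 1 - sum((yte - pr)^2) / sum((yte - mean(y[m$tr]))^2))
    }
  })
  n_models <- length(models)
  mean_rank <- rank_sum / n_models
  ranked <- data.frame(feature = names(mean_rank), mean_rank = mean_rank,
                       selection_count = sel_count, stringsAsFactors = FALSE)
  ranked <- ranked[order(ranked$mean_rank), ]
  rownames(ranked) <- NULL
  selected <- names(sel_count)[sel_count > n_models / 2]
  selected <- selected[order(mean_rank[selected])]
  new_selection_report(cfg$method, food, ranked, selected,
                       q2 = mean(q2s), counts = sel_count, n_models = n_models)
}

#' Bagged LASSO variable selection with an elbow-point cutoff
#'
#' Fits an L1-penalized linear regression on `n_bootstrap` row resamples,
#' tuning the penalty on each by `cv_folds_lasso`-fold cross-validation
#' (penalty at the CV minimum by default), and counts how often each feature
#' enters with a nonzero coefficient. Features whose selection frequency is
#' at or above the frequency at the [detect_elbow()] cutoff of the
#' descending frequency curve form the `selected_set`.
#'
#' @inheritParams rdcv_select
#' @param cfg a [selector_config()] with method `"lasso_bag"`.
#' @return a `selection_report` including the `frequency_curve` and
#'   `elbow_index`.
#' @export
lasso_bag_select <- function(X, y, cfg, food = NULL) {
  stopifnot(inherits(cfg, "selector_config"))
  if (cfg$method != "lasso_bag") stop("`cfg$method` must be lasso_bag")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 20) stop("bagged LASSO needs at least 20 samples")
  if (all(y == 0)) stop("`y` is identically zero")
  counts <- setNames(numeric(ncol(X)), colnames(X))
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      foldid <- sample(rep_len(seq_len(cfg$cv_folds_lasso), n))
      fit <- glmnet::cv.glmnet(X[idx, , drop = FALSE], y[idx], foldid = foldid,
                               nlambda = cfg$nlambda, standardize = TRUE)
      lam <- if (cfg$lambda_choice == "min") fit$lambda.min else fit$lambda.1se
      cf <- as.matrix(coef(fit, s = lam))[-1, 1]
      counts[cf != 0] <- counts[cf != 0] + 1
    }
  })
  curve <- counts[order(-counts, names(counts))] # deterministic tie order
  cut <- detect_elbow(unname(curve), prominence = cfg$prominence)
  selected <- names(curve)[curve >= curve[cut] & curve > 0]
  ranked <- data.frame(feature = names(curve), frequency = unname(curve),
                       stringsAsFactors = FALSE)
  new_selection_report("lasso_bag", food, ranked, selected,
                       counts = counts, frequency_curve = unname(curve),
                       elbow_index = cut)
}

#' Elbow-point detection on a descending frequency curve
#'
#' Computes the successive drops `d_i = f_i - f_(i+1)` of a non-increasing
#' curve and flags as elbow points the local maxima of `d` that exceed a
#' prominence threshold. The default `"relative"` rule requires a drop to
#' exceed both the mean drop and 80% of the largest drop, so only drops
#' comparable to the sharpest one qualify; the `"mean_sd"` variant uses
#' `mean(d) + 2 * SD(d)`. The cutoff returned is the index of the **last**
#' qualifying drop, so everything strictly after it is excluded; if no drop
#' qualifies (e.g. a smooth or flat curve), the single largest drop is used
#' as a fallback.
#'
#' @param frequencies non-increasing numeric vector (length >= 2).
#' @param prominence `"relative"` (default) or `"mean_sd"`.
#' @return the cutoff index: positions `1..cutoff` are retained.
#' @examples
#' detect_elbow(c(900, 850, 820, 400, 390, 380)) # 3
#' detect_elbow(c(900, 500, 480, 460, 100, 90)) # 4: last sharp drop wins
#' @export
detect_elbow <- function(frequencies, prominence = c("relative", "mean_sd")) {
  prominence <- match.arg(prominence)
  if (length(frequencies) < 2) stop("curve must have length >= 2")
  if (any(diff(frequencies) > 0)) stop("`frequencies` must be non-increasing")
  d <- -diff(frequencies)
  thr <- if (prominence == "relative") {
    max(mean(d), 0.8 * max(d))
  } else {
    mean(d) + 2 * sd(d)
  }
  m <- length(d)
  local_max <- vapply(seq_len(m), function(i) {
    (i == 1 || d[i] >= d[i - 1]) && (i == m || d[i] >= d[i + 1])
  }, logical(1))
  cand <- which(d > thr & local_max)
  if (length(cand) == 0) which.max(d) else max(cand)
}

#' Multi-method consensus feature set
#'
#' @param reports list of `selection_report`s for the same food, one per
#'   distinct method.
#' @param min_methods minimum number of methods that must select a feature
#'   (default 2).
#' @return character vector of features selected by at least `min_methods`
#'   distinct methods.
#' @export
consensus <- function(reports, min_methods = 2) {
  stopifnot(length(reports) >= 2)
  methods <- vapply(reports, function(r) r$method, character(1))
  if (anyDuplicated(methods)) stop("duplicated method in reports: ",
                                   paste(methods[duplicated(methods)], collapse = ", "))
  foods <- unique(unlist(lapply(reports, function(r) r$food)))
  if (length(foods) > 1) stop("reports mix foods: ", paste(foods, collapse = ", "))
  tab <- table(unlist(lapply(reports, function(r) unique(r$selected_set))))
  as.character(sort(names(tab)[tab >= min_methods]))
}
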