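# Orchestration: stage sequencing with a single master seed, plain-text
# artifact round-trips, a deterministic manifest, and truth scoring.

#' Analytic moments of the zero-inflated log-normal intake
#'
#' @param p_zero,meanlog,sdlog mixture parameters.
#' @return list with `mean`, `sd` and `median` of the mixture.
#' @export
ziln_moments <- function(p_zero, meanlog, sdlog) {
  m1 <- (1 - p_zero) * exp(meanlog + sdlog^2 / 2)
  m2 <- (1 - p_zero) * exp(2 * meanlog + 2 * sdlog^2)
  list(mean = m1, sd = sqrt(m2 - m1^2),
       median = if (p_zero >= 0.5) 0 else
         qlnorm((0.5 - p_zero) / (1 - p_zero), meanlog, sdlog))
}

#' The package's standard simulation scenario
#'
#' A single-collection cohort of `n` participants and `p` features with
#' `n_truth` planted SSB-associated metabolites at a standardized effect of
#' `effect` SD of log intensity per SD of raw intake (the per-g/d slope is
#' `effect / SD(intake)`, using the analytic intake SD), detection-limit
#' censoring at the 10% quantile, batch location/scale effects, and one
#' truth metabolite driving BMI at 1 unit per SD of log intensity.
#'
#' @param seed master seed.
#' @param n participants.
#' @param p features.
#' @param n_truth planted food-associated features.
#' @param effect standardized intake effect (SD per SD).
#' @param food exposure carrying the planted effects.
#' @param adiposity_coef coefficient of the first truth feature on BMI.
#' @param ... further overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
standard_sim_config <- function(seed = 1, n = 300, p = 500, n_truth = 10,
                                effect = 0.3, food = "ssb",
                                adiposity_coef = 1.0, ...) {
  ip <- .default_intake_params[[food]]
  sd_x <- ziln_moments(ip$p_zero, ip$meanlog, ip$sdlog)$sd
  idx <- unique(round(seq(1, p, length.out = n_truth)))
  te <- list()
  te[[food]] <- data.frame(feature = idx, beta = rep(effect / sd_x, length(idx)))
  ae <- if (adiposity_coef != 0) {
    list(bmi = data.frame(feature = idx[1], coef = adiposity_coef))
  } else list()
  sim_config(n_participants = n, design = "adolescent_single", n_features = p,
             n_batches = 4, true_effects = te, adiposity_effects = ae,
             intake_correlation = 0.65, lod_quantile = 0.1, seed = seed, ...)
}

#' Scaled-down selector profile
#'
#' The selector settings used by the package's simulation studies: 10
#' repetitions of the double-CV scheme and 200 bootstrap LASSO fits
#' (reduced from the defaults of 50 and 1000), 100-tree forests eliminating
#' half the variables per round, and a 50-knot penalty path. See the
#' methods vignette for the rationale.
#'
#' @param method selector method.
#' @param seed RNG seed.
#' @param ... overrides passed to [selector_config()].
#' @return a [selector_config()].
#' @export
scaled_selector_config <- function(method, seed = 1, ...) {
  defaults <- list(
    rdcv_pls = list(n_repetitions = 10, drop_fraction = 0.2),
    rdcv_rf = list(n_repetitions = 10, drop_fraction = 0.5, num_trees = 100),
    lasso_bag = list(n_bootstrap = 200, nlambda = 50)
  )[[method]]
  args <- utils::modifyList(c(list(method = method, seed = seed), defaults),
                            list(...))
  do.call(selector_config, args)
}

# Covariates of the adiposity models, per design.
.adiposity_covariates <- list(
  children_repeated = c("age", "sex", "energy", "birthweight", "anthro_time_diff"),
  adolescent_single = c("age", "sex", "energy", "birthweight", "anthro_time_diff",
                        "met_hours", "smoking", "alcohol"),
  adult_plasma = c("age", "sex", "energy", "birthweight", "anthro_time_diff",
                   "met_hours", "smoking", "alcohol", "time_gap", "n_assessments")
)

#' Configuration of a full pipeline run
#'
#' @param out_dir output directory for artifacts.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param seed master seed fanned out to every stage via [derive_seed()].
#' @param foods intake exposures analysed.
#' @param stages named logical toggles for
#'   `simulate, preprocess, select, associate, adiposity`.
#' @param missing_threshold consumer-missingness filter threshold.
#' @param imputation `"half_min"`, `"quantile_regression"` or
#'   `"random_forest"`.
#' @param batch_correct apply [correct_batch()] after standardization.
#' @param knn_k neighbours for covariate imputation.
#' @param selectors selection methods to run.
#' @param selector_opts named list of per-method overrides for
#'   [scaled_selector_config()].
#' @param alpha nominal significance level for the adiposity stage.
#' @param vif_threshold VIF pruning threshold.
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("sweetmet_run_"),
                       sim = standard_sim_config(),
                       seed = 1,
                       foods = "ssb",
                       stages = c(simulate = TRUE, preprocess = TRUE,
                                  select = TRUE, associate = TRUE,
                                  adiposity = TRUE),
                       missing_threshold = 0.30,
                       imputation = c("half_min", "quantile_regression",
                                      "random_forest"),
                       batch_correct = TRUE,
                       knn_k = 10,
                       selectors = c("rdcv_pls", "rdcv_rf", "lasso_bag"),
                       selector_opts = list(),
                       alpha = 0.05,
                       vif_threshold = 10) {
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, seed = as.integer(seed),
                 foods = foods, stages = stages,
                 missing_threshold = missing_threshold,
                 imputation = match.arg(imputation),
                 batch_correct = batch_correct, knn_k = knn_k,
                 selectors = selectors, selector_opts = selector_opts,
                 alpha = alpha, vif_threshold = vif_threshold),
            class = "run_config")
}

#' Run the full discovery pipeline
#'
#' Executes the enabled stages in the fixed order simulate -> preprocess ->
#' select -> associate -> adiposity, writing plain-text artifacts and a
#' deterministic manifest (stage counts, per-stage seeds, MD5 checksums of
#' every artifact) to `cfg$out_dir`. Disabling a stage whose output a later
#' enabled stage needs is an error.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list of class `sweetmet_run` holding the in-memory
#'   stage results (`cohort`, `fm`, `truth`, `retained`, `reports`,
#'   `consensus`, `associations`, `adiposity`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) isTRUE(cfg$stages[[s]])
  manifest <- list(schema_version = "1.0", design = cfg$sim$design,
                   master_seed = cfg$seed, stages = list())
  res <- list(config = cfg)
  art <- function(name) file.path(cfg$out_dir, name)
  written <- character()

  if (on("simulate")) {
    cohort <- generate_cohort(cfg$sim)
    gm <- generate_metabolome(cfg$sim, cohort)
    cohort <- generate_adiposity(cohort, gm$fm, cfg$sim)
    fm <- inject_missingness(gm$fm, cfg$sim)
    write_cohort(cohort, art("phenotypes.csv"))
    write_feature_matrix(fm, art("features.tsv"), art("batches.tsv"))
    write_truth(gm$truth, art("truth.json"))
    written <- c(written, "phenotypes.csv", "features.tsv", "batches.tsv",
                 "truth.json")
    res$cohort <- cohort
    res$fm_raw <- fm
    res$truth <- gm$truth
    manifest$stages$simulate <- list(
      seed = derive_seed(cfg$seed, "cohort"), n_samples = nrow(cohort),
      n_features = ncol(fm$values),
      n_missing_cells = sum(is.na(fm$values)))
  }

  if (on("preprocess")) {
    if (is.null(res$cohort)) stop("preprocess needs the simulate stage's artifacts")
    consumers <- consumers_of(res$cohort, cfg$foods)
    fr <- filter_missing(res$fm_raw, consumers, cfg$missing_threshold)
    pseed <- derive_seed(cfg$seed, "preprocess")
    fmi <- switch(cfg$imputation,
                  half_min = impute_half_min(fr$fm),
                  quantile_regression = impute_censored_quantile(fr$fm, seed = pseed),
                  random_forest = impute_forest(fr$fm, seed = pseed))
    fms <- log_standardize(fmi)
    fmc <- if (cfg$batch_correct) correct_batch(fms) else fms
    cohort_i <- knn_impute_covariates(res$cohort, k = cfg$knn_k)
    write_feature_matrix(fmc, art("analysis_matrix.tsv"), art("analysis_batches.tsv"))
    prov <- list(dropped_features = fr$dropped,
                 retained_per_food = lapply(fr$retained, length),
                 imputation = cfg$imputation,
                 batch_correct = cfg$batch_correct)
    jsonlite::write_json(prov, art("preprocess_log.json"), auto_unbox = TRUE)
    written <- c(written, "analysis_matrix.tsv", "analysis_batches.tsv",
                 "preprocess_log.json")
    res$fm <- fmc
    res$retained <- fr$retained
    res$cohort_imputed <- cohort_i
    manifest$stages$preprocess <- list(
      seed = pseed, n_dropped = length(fr$dropped),
      n_features_out = ncol(fmc$values))
  }

  if (on("select")) {
    if (is.null(res$fm)) stop("select needs the preprocess stage's artifacts")
    res$reports <- list()
    res$consensus <- list()
    for (food in cfg$foods) {
      y <- res$cohort[[food]]
      feats <- intersect(res$retained[[food]], colnames(res$fm$values))
      X <- res$fm$values[res$cohort$sample_id, feats, drop = FALSE]
      reports <- list()
      for (m in cfg$selectors) {
        scfg <- do.call(scaled_selector_config,
                        c(list(method = m,
                               seed = derive_seed(cfg$seed, switch(m,
                                 rdcv_pls = "select_pls", rdcv_rf = "select_rf",
                                 lasso_bag = "select_lasso"))),
                          cfg$selector_opts[[m]] %||% list()))
        rep_m <- if (m == "lasso_bag") lasso_bag_select(X, y, scfg, food = food)
                 else rdcv_select(X, y, scfg, food = food)
        reports[[m]] <- rep_m
        jsonlite::write_json(
          list(method = m, food = food, selected = rep_m$selected_set,
               q2 = rep_m$q2, elbow_index = rep_m$elbow_index),
          art(sprintf("selection_%s_%s.json", food, m)), auto_unbox = TRUE,
          digits = NA)
        written <- c(written, sprintf("selection_%s_%s.json", food, m))
        if (!is.null(rep_m$frequency_curve)) {
          write.table(data.frame(feature = rep_m$ranked_features$feature,
                                 frequency = rep_m$ranked_features$frequency),
                      art(sprintf("frequency_%s_%s.tsv", food, m)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          written <- c(written, sprintf("frequency_%s_%s.tsv", food, m))
        }
      }
      cons <- consensus(reports)
      res$reports[[food]] <- reports
      res$consensus[[food]] <- cons
      jsonlite::write_json(list(food = food, consensus = cons),
                           art(sprintf("consensus_%s.json", food)),
                           auto_unbox = TRUE)
      written <- c(written, sprintf("consensus_%s.json", food))
    }
    manifest$stages$select <- list(
      seeds = setNames(lapply(cfg$selectors, function(m)
        derive_seed(cfg$seed, switch(m, rdcv_pls = "select_pls",
                                     rdcv_rf = "select_rf",
                                     lasso_bag = "select_lasso"))), cfg$selectors),
      n_selected = lapply(res$reports, function(rs)
        lapply(rs, function(r) length(r$selected_set))),
      n_consensus = lapply(res$consensus, length))
  }

  if (on("associate")) {
    if (is.null(res$consensus)) stop("associate needs the select stage's consensus artifact")
    tabs <- lapply(cfg$foods, function(food) {
      associate(res$fm, res$cohort_imputed, res$consensus[[food]], food,
                cfg$sim$design)
    })
    assoc <- do.call(rbind, tabs)
    class(assoc) <- c("association_table", "data.frame")
    write.csv(as.data.frame(assoc), art("associations.csv"), row.names = FALSE)
    written <- c(written, "associations.csv")
    res$associations <- assoc
    manifest$stages$associate <- list(
      n_tested = nrow(assoc), n_significant = sum(assoc$q < 0.05))
  }

  if (on("adiposity")) {
    if (is.null(res$associations)) stop("adiposity needs the associate stage's artifacts")
    sig <- unique(res$associations$feature[res$associations$q < 0.05])
    res$adiposity <- list()
    if (length(sig) >= 1) {
      covs <- .adiposity_covariates[[cfg$sim$design]]
      cov_df <- as.data.frame(res$cohort_imputed)[, covs, drop = FALSE]
      M <- res$fm$values[res$cohort$sample_id, sig, drop = FALSE]
      out_mat <- as.matrix(as.data.frame(res$cohort)[, .outcomes])
      a_adj <- adjusted_alpha(out_mat, cfg$alpha)
      combined <- list()
      for (out in .outcomes) {
        rep_o <- fit_adiposity(res$cohort[[out]], M, cov_df, cfg$sim$design,
                               participant_id = res$cohort$participant_id,
                               outcome_name = out, alpha_adjusted = a_adj,
                               vif_threshold = cfg$vif_threshold)
        if (length(rep_o$retained$feature) >= 2) {
          rep_o$sensitivity <- adaptive_enet_sensitivity(
            res$cohort[[out]], M[, rep_o$retained$feature, drop = FALSE],
            cov_df, seed = derive_seed(cfg$seed, "enet"))
        }
        res$adiposity[[out]] <- rep_o
        combined[[out]] <- data.frame(outcome = out, rep_o$retained,
                                      stringsAsFactors = FALSE)
        jsonlite::write_json(
          list(outcome = out, alpha_adjusted = a_adj,
               retained = rep_o$retained, removal_trace = rep_o$removal_trace,
               sensitivity_nonzero = rep_o$sensitivity),
          art(sprintf("adiposity_%s.json", out)), auto_unbox = TRUE,
          dataframe = "columns", digits = NA)
        written <- c(written, sprintf("adiposity_%s.json", out))
      }
      comb <- do.call(rbind, combined)
      write.csv(comb[, c("outcome", "feature", "beta", "ci_low", "ci_high",
                         "p", "significant")],
                art("adiposity_models.csv"), row.names = FALSE)
      written <- c(written, "adiposity_models.csv")
      manifest$stages$adiposity <- list(
        alpha_adjusted = a_adj, n_features_in = length(sig),
        n_significant = sum(comb$significant))
    } else {
      manifest$stages$adiposity <- list(alpha_adjusted = NA, n_features_in = 0,
                                        n_significant = 0)
    }
  }

  written <- sort(unique(written))
  sums <- tools::md5sum(file.path(cfg$out_dir, written))
  manifest$artifacts <- setNames(as.list(unname(sums)), written)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "sweetmet_run"
  invisible(res)
}

#' @method print sweetmet_run
#' @export
print.sweetmet_run <- function(x, ...) {
  cat("<sweetmet_run> stages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  for (food in names(x$consensus %||% list())) {
    cat(sprintf("  %s consensus: %d features\n", food, length(x$consensus[[food]])))
  }
  if (!is.null(x$associations)) {
    cat(sprintf("  associations: %d tested, %d at q < 0.05\n",
                nrow(x$associations), sum(x$associations$q < 0.05)))
  }
  invisible(x)
}

#' Sensitivity and false-discovery proportion of a selected set
#'
#' @param selected character vector of selected feature ids.
#' @param truth_features character vector of truly associated feature ids.
#' @return list with `sensitivity` (|selected & truth| / |truth|) and
#'   `fdp` (|selected \ truth| / |selected|, 0 for an empty selection).
#' @export
score_selection <- function(selected, truth_features) {
  tp <- length(intersect(selected, truth_features))
  list(sensitivity = if (length(truth_features)) tp / length(truth_features) else NA,
       fdp = if (length(selected)) (length(selected) - tp) / length(selected) else 0)
}

#' Score a pipeline run against the generator's ground truth
#'
#' For each food with planted effects: consensus-set sensitivity and FDP,
#' association-stage sensitivity/FDP at `q < 0.05`, and the per-truth-feature
#' coefficient bias of the association estimator on the analysis scale (the
#' planted per-g/d slope divided by the log-SD used in standardization).
#' Bias is evaluated over **all** planted features still present in the
#' analysis matrix — truth features absent from the run's association table
#' (not selected by the consensus) are fitted with the same design-locked
#' model, so the bias summary measures the estimator, not the selection.
#' For the adiposity stage: the fraction of truly outcome-driving
#' metabolites flagged significant.
#'
#' @param run a `sweetmet_run` from [run_pipeline()].
#' @param truth a `truth_table` (defaults to the run's own).
#' @return a list with per-food metrics and adiposity flag recovery.
#' @export
score_against_truth <- function(run, truth = run$truth) {
  stopifnot(inherits(run, "sweetmet_run"), inherits(truth, "truth_table"))
  scales <- attr(run$fm, "log_scale")
  design <- run$config$sim$design
  zq <- qnorm(0.975)
  foods <- lapply(names(truth$foods), function(food) {
    tf <- truth$foods[[food]]
    if (!all(tf$feature %in% c(colnames(run$fm_raw$values)))) {
      stop("truth features not present in the generated matrix")
    }
    cons <- score_selection(run$consensus[[food]], tf$feature)
    at <- run$associations[run$associations$food == food, , drop = FALSE]
    disc <- at$feature[at$q < 0.05]
    assoc_score <- score_selection(disc, tf$feature)
    hit <- at[match(tf$feature, at$feature), , drop = FALSE]
    refit <- setdiff(intersect(tf$feature, colnames(run$fm$values)),
                     at$feature)
    if (length(refit)) {
      extra <- associate(run$fm, run$cohort_imputed, refit, food, design)
      hit[match(extra$feature, tf$feature), ] <- extra[, names(hit)]
    }
    ok <- !is.na(hit$beta) & tf$feature %in% names(scales)
    beta_true <- tf$beta / scales[tf$feature]
    se_hat <- (hit$ci_high - hit$ci_low) / (2 * zq)
    bias <- hit$beta - beta_true
    list(food = food,
         consensus_sensitivity = cons$sensitivity, consensus_fdp = cons$fdp,
         assoc_sensitivity = assoc_score$sensitivity, assoc_fdp = assoc_score$fdp,
         mean_bias = mean(bias[ok]), mean_se = mean(se_hat[ok]),
         mean_bias_over_se = mean(bias[ok]) / mean(se_hat[ok]),
         bias = setNames(as.numeric(bias), tf$feature),
         se = setNames(as.numeric(se_hat), tf$feature),
         n_scored = sum(ok))
  })
  names(foods) <- names(truth$foods)
  adip <- NULL
  if (length(truth$outcomes) && length(run$adiposity)) {
    flags <- unlist(lapply(names(truth$outcomes), function(out) {
      rep_o <- run$adiposity[[out]]
      if (is.null(rep_o)) return(NULL)
      tf <- truth$outcomes[[out]]$feature
      tf %in% rep_o$retained$feature[rep_o$retained$significant]
    }))
    adip <- list(flag_recovery = if (length(flags)) mean(flags) else NA)
  }
  list(foods = foods, adiposity = adip)
}
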