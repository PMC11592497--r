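# End-to-end pipeline ----------------------------------------------------------
#
# Orchestrates: simulate -> preprocess -> split -> tune -> validate
# (repeated-CV fits + holdout evaluation) -> explain (SHAP, SurvSHAP(t),
# rank frequency, group force) -> CPH comparison on the union of top
# features -> manifest. Every stage draws its randomness from seeds
# derived deterministically from the master seed, so a rerun with the
# same configuration reproduces every artifact byte for byte.

#' Pipeline configuration
#'
#' The `reduced` profile is the desk-scale configuration: a trimmed
#' Bayesian-optimisation budget and subsampled explanation sets, with the
#' statistical structure of the full workflow intact. The `full` profile
#' uses the full-scale budgets (50 + 128 tuning evaluations, 64
#' permutations, all holdout observations and models explained).
#'
#' @param cohort A [cohort_spec()] to simulate, or a path to a raw cohort
#'   CSV written by [write_cohort_csv()].
#' @param outdir Output directory for artifacts.
#' @param seed Master seed; every stage seed derives from it.
#' @param profile `"reduced"` or `"full"`.
#' @param split_ratio Train fraction (default 0.6).
#' @param cv_k,cv_repeats Repeated-CV geometry (default 10 x 10).
#' @param families Model families to run (`"rsf"`, `"boosted_cox"`).
#' @param censor_quantile Follow-up outlier-censoring quantile.
#' @param time_bins Time-quantile strata count for splitting.
#' @param tune Run Bayesian hyperparameter optimisation (if `FALSE`, the
#'   default configurations are used).
#' @param fit_cph_comparison Fit the CPH comparison on the union of each
#'   family's top-5 features.
#' @param hpo,explain Optional lists overriding profile-derived budgets
#'   (`hpo$n_init`, `hpo$n_sampling_runs`; `explain$shap_n_perm`,
#'   `explain$shap_max_obs`, `explain$background_size`,
#'   `explain$survshap_models`, `explain$survshap_max_obs`,
#'   `explain$grid_max`, `explain$survshap_n_perm`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), outdir = tempfile("run_"),
                            seed = 1L, profile = c("reduced", "full"),
                            split_ratio = 0.6, cv_k = 10L, cv_repeats = 10L,
                            families = c("rsf", "boosted_cox"),
                            censor_quantile = 0.995, time_bins = 5L,
                            tune = TRUE, fit_cph_comparison = TRUE,
                            hpo = list(), explain = list()) {
  profile <- match.arg(profile)
  known <- c("rsf", "boosted_cox")
  if (length(families) == 0L || !all(families %in% known)) {
    stop_field("families", sprintf("must be drawn from {%s}",
                                   paste(known, collapse = ", ")))
  }
  assert_number(split_ratio, "split_ratio", 0, 1, open_lower = TRUE)
  assert_number(cv_k, "cv_k", lower = 2, integer = TRUE)
  assert_number(cv_repeats, "cv_repeats", lower = 1, integer = TRUE)
  defaults <- if (profile == "full") {
    list(hpo = list(n_init = 50L, n_sampling_runs = 128L),
         explain = list(shap_n_perm = 64L, shap_max_obs = Inf,
                        background_size = 100L, survshap_models = Inf,
                        survshap_max_obs = Inf, grid_max = 200L,
                        survshap_n_perm = 64L))
  } else {
    list(hpo = list(n_init = 8L, n_sampling_runs = 8L),
         explain = list(shap_n_perm = 6L, shap_max_obs = 20L,
                        background_size = 12L, survshap_models = 3L,
                        survshap_max_obs = 12L, grid_max = 24L,
                        survshap_n_perm = 6L))
  }
  cfg <- structure(list(
    cohort = cohort, outdir = outdir, seed = as.integer(seed),
    profile = profile, split_ratio = split_ratio,
    cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
    families = families, censor_quantile = censor_quantile,
    time_bins = as.integer(time_bins), tune = tune,
    fit_cph_comparison = fit_cph_comparison,
    hpo = utils::modifyList(defaults$hpo, hpo),
    explain = utils::modifyList(defaults$explain, explain)
  ), class = "pipeline_config")
  if (is.character(cfg$cohort) && !file.exists(cfg$cohort)) {
    stop_field("cohort", sprintf("input file '%s' does not exist",
                                 cfg$cohort))
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `cohort_csv` field names an input file, otherwise the default synthetic
#' cohort specification (optionally reseeded by `cohort_seed`) is used.
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(...)
  for (nm in c("outdir", "seed", "profile", "split_ratio", "cv_k",
               "cv_repeats", "families", "censor_quantile", "time_bins",
               "tune", "fit_cph_comparison", "hpo", "explain")) {
    if (!is.null(y[[nm]]) && is.null(args[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$cohort_csv)) {
    args$cohort <- y$cohort_csv
  } else if (!is.null(y$cohort_seed)) {
    args$cohort <- cohort_spec(seed = y$cohort_seed)
  }
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  canon <- config
  canon$cohort <- if (is.character(canon$cohort)) canon$cohort else
    unclass(canon$cohort)
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end workflow
#'
#' Executes every stage in order, writes all tabular artifacts as CSV into
#' `config$outdir`, and records a JSON manifest with artifact paths, stage
#' status, seeds, and the configuration hash. A failing stage is marked
#' failed and downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` and the in-memory `results`
#'   of each stage.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   profile = config$profile, stages = list(),
                   artifacts = list())
  results <- new.env(parent = emptyenv())
  failed <- FALSE

  art <- function(name, file) {
    path <- file.path(config$outdir, file)
    manifest$artifacts[[name]] <<- path
    path
  }
  run_stage <- function(name, fn) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(list(value = fn(), status = "ok"),
                    error = function(e) list(value = NULL, status = "failed",
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- res[setdiff(names(res), "value")]
    if (res$status == "failed") failed <<- TRUE
    invisible(res$value)
  }

  run_stage("simulate", function() {
    raw <- if (is.character(config$cohort)) {
      read_cohort_csv(config$cohort)
    } else {
      co <- generate_cohort(config$cohort)
      co <- inject_missingness(co, config$cohort$missingness_rates,
                               seed = derive_seed(config$seed, 11L))
      co
    }
    write_cohort_csv(raw, art("cohort_raw", "cohort_raw.csv"))
    results$raw <- raw
  })

  run_stage("preprocess", function() {
    imputed <- impute_chained(results$raw,
                              seed = derive_seed(config$seed, 12L))
    engineered <- engineer_features(imputed)
    cens <- censor_followup_outliers(engineered, config$censor_quantile)
    jsonlite::write_json(
      list(threshold = cens$threshold, n_affected = cens$n_affected,
           n_events_affected = cens$n_events_affected),
      art("outlier_censoring", "outlier_censoring.json"),
      auto_unbox = TRUE, digits = NA)
    corr <- prune_correlated(cens$dataset)
    write.csv(corr, art("correlation_report", "correlation_report.csv"),
              row.names = FALSE)
    summ <- cohort_summary(cens$dataset)
    write.csv(summ$groups, art("cohort_summary", "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(cens$dataset),
              art("dataset_engineered", "dataset_engineered.csv"),
              row.names = FALSE)
    results$dataset <- cens$dataset
    results$censoring <- cens[c("threshold", "n_affected",
                                "n_events_affected")]
    results$summary <- summ
  })

  run_stage("split", function() {
    ds <- results$dataset
    sdef <- strata_definition(time_bins = config$time_bins)
    part <- stratified_partition(ds$time, ds$status, ds$disease_group,
                                 ratio = config$split_ratio, strata = sdef,
                                 seed = derive_seed(config$seed, 21L))
    split_df <- data.frame(observation_id = seq_len(nrow(ds)),
                           partition = ifelse(seq_len(nrow(ds)) %in%
                                                part$train_ids,
                                              "train", "test"))
    write.csv(split_df, art("split", "split.csv"), row.names = FALSE)
    train <- ds[part$train_ids, , drop = FALSE]
    plan <- repeated_cv_folds(train$time, train$status, train$disease_group,
                              k = config$cv_k, repeats = config$cv_repeats,
                              strata = sdef,
                              seed = derive_seed(config$seed, 22L))
    write_fold_plan_csv(plan, art("fold_plan", "fold_plan.csv"))
    tune_folds <- repeated_cv_folds(train$time, train$status,
                                    train$disease_group, k = 3L,
                                    repeats = 1L, strata = sdef,
                                    seed = derive_seed(config$seed, 23L))
    results$train <- train
    results$holdout <- ds[part$test_ids, , drop = FALSE]
    results$plan <- plan
    results$tune_folds <- tune_folds$assignment[, 1]
  })

  run_stage("tune", function() {
    best <- list()
    for (fam in config$families) {
      if (config$tune) {
        objective <- make_cv_objective(results$train, results$tune_folds,
                                       family = fam,
                                       seed = derive_seed(config$seed, 31L))
        space <- if (fam == "rsf") rsf_search_space() else
          boosted_cox_search_space()
        bo <- bayesian_optimize(
          objective, space,
          bayes_opt_config(kappa = 3.5,
                           n_sampling_runs = config$hpo$n_sampling_runs,
                           n_init = config$hpo$n_init,
                           seed = derive_seed(config$seed, 32L)))
        write_tuning_result(
          bo, trace_csv = art(paste0("tuning_trace_", fam),
                              sprintf("tuning_trace_%s.csv", fam)),
          best_json = art(paste0("tuning_best_", fam),
                          sprintf("tuning_best_%s.json", fam)))
        best[[fam]] <- bo$best_setting
      } else {
        best[[fam]] <- NULL  # family defaults
      }
    }
    results$best_settings <- best
  })

  run_stage("validate", function() {
    train <- results$train
    plan <- results$plan
    models <- list()
    records <- list()
    for (fam in config$families) {
      setting <- results$best_settings[[fam]]
      fam_models <- list()
      recs <- list()
      for (r in seq_len(plan$repeats)) {
        for (f in seq_len(plan$k)) {
          seed_rf <- derive_seed(config$seed,
                                 1000L + 100L * match(fam, config$families) +
                                   10L * r + f)
          tr <- train[plan$assignment[, r] != f, , drop = FALSE]
          va <- train[plan$assignment[, r] == f, , drop = FALSE]
          model <- if (fam == "rsf") {
            cfg <- if (is.null(setting)) rsf_config() else
              do.call(rsf_config, setting)
            fit_rsf(tr, cfg, seed = seed_rf)
          } else {
            cfg <- if (is.null(setting)) boosted_cox_config() else
              do.call(boosted_cox_config, setting)
            fit_boosted_cox(tr, cfg, validation = va, seed = seed_rf)
          }
          model$model_id <- sprintf("%s_r%02d_f%02d", fam, r, f)
          model$cv_cell <- c(rep = r, fold = f)
          fam_models[[length(fam_models) + 1L]] <- model
          recs[[length(recs) + 1L]] <- data.frame(
            model_id = model$model_id, family = fam, rep = r, fold = f,
            seed = seed_rf,
            num_rounds_used = if (is.null(model$meta$num_rounds_used))
              NA_integer_ else model$meta$num_rounds_used,
            validation_c_index = harrell_c_index(va$time, va$status,
                                                 predict_risk(model, va)),
            stringsAsFactors = FALSE)
        }
      }
      models[[fam]] <- fam_models
      rec <- do.call(rbind, recs)
      names(rec)[names(rec) == "rep"] <- "repeat"
      write.csv(rec, art(paste0("models_", fam),
                         sprintf("models_%s.csv", fam)), row.names = FALSE)
      records[[fam]] <- rec
    }
    perf <- evaluate_ensemble(unlist(models, recursive = FALSE),
                              results$holdout)
    # per-family validation summary alongside holdout
    write_performance_summary(
      perf, csv_path = art("performance_summary", "performance_summary.csv"),
      json_path = art("performance_summary_json", "performance_summary.json"))
    write.csv(perf$per_model, art("per_model_performance",
                                  "per_model_performance.csv"),
              row.names = FALSE)
    results$models <- models
    results$records <- records
    results$performance <- perf
  })

  run_stage("explain", function() {
    holdout <- results$holdout
    ex <- config$explain
    n_obs <- min(nrow(holdout), ex$shap_max_obs)
    obs_idx <- with_seed(derive_seed(config$seed, 41L),
                         sort(sample.int(nrow(holdout), n_obs)))
    X <- holdout[obs_idx, , drop = FALSE]
    results$explained_idx <- obs_idx
    aggregates <- list()
    importance <- list()
    for (fam in config$families) {
      mats <- list()
      imps <- list()
      for (mi in seq_along(results$models[[fam]])) {
        model <- results$models[[fam]][[mi]]
        r <- model$cv_cell[["rep"]]
        f <- model$cv_cell[["fold"]]
        tr <- results$train[results$plan$assignment[, r] != f, ,
                            drop = FALSE]
        bg_idx <- with_seed(derive_seed(config$seed, 42L + mi),
                            sort(sample.int(nrow(tr),
                                            min(nrow(tr),
                                                ex$background_size))))
        sm <- shap_attributions(model, X, tr[bg_idx, , drop = FALSE],
                                method = "sampling",
                                n_perm = ex$shap_n_perm,
                                seed = derive_seed(config$seed,
                                                   5000L + 100L *
                                                     match(fam,
                                                           config$families) +
                                                     mi))
        mats[[mi]] <- sm
        imps[[mi]] <- shap_importance(sm)
      }
      agg <- aggregate_shap_over_models(mats)
      write_shap_csv(agg, art(paste0("shap_aggregated_", fam),
                              sprintf("shap_aggregated_%s.csv", fam)))
      write.csv(agg$ranking, art(paste0("shap_ranking_", fam),
                                 sprintf("shap_ranking_%s.csv", fam)),
                row.names = FALSE)
      rf <- top_k_rank_frequency(imps, k = 5L)
      write.csv(rf, art(paste0("rank_frequency_", fam),
                        sprintf("rank_frequency_%s.csv", fam)),
                row.names = FALSE)
      force <- group_force_summary(agg, X$disease_group,
                                   valid_groups = DISEASE_GROUPS)
      write.csv(force, art(paste0("group_force_", fam),
                           sprintf("group_force_%s.csv", fam)),
                row.names = FALSE)
      aggregates[[fam]] <- agg
      importance[[fam]] <- imps
    }
    results$shap_aggregates <- aggregates
    results$shap_importance <- importance

    if ("rsf" %in% config$families) {
      grid <- time_grid(results$train$time, results$train$status,
                        max_points = ex$grid_max)
      n_mod <- min(length(results$models$rsf), ex$survshap_models)
      n_sobs <- min(nrow(X), ex$survshap_max_obs)
      Xs <- X[seq_len(n_sobs), , drop = FALSE]
      globals <- lapply(seq_len(n_mod), function(mi) {
        model <- results$models$rsf[[mi]]
        r <- model$cv_cell[["rep"]]
        f <- model$cv_cell[["fold"]]
        tr <- results$train[results$plan$assignment[, r] != f, ,
                            drop = FALSE]
        bg_idx <- with_seed(derive_seed(config$seed, 42L + mi),
                            sort(sample.int(nrow(tr),
                                            min(nrow(tr),
                                                ex$background_size))))
        curves <- survshap_curves(model, Xs, tr[bg_idx, , drop = FALSE],
                                  grid = grid, method = "sampling",
                                  n_perm = ex$survshap_n_perm,
                                  seed = derive_seed(config$seed,
                                                     7000L + mi))
        global_survshap(curves)
      })
      agg_global <- aggregate_survshap_over_models(globals)
      write_survshap_csv(agg_global, art("survshap_global_rsf",
                                         "survshap_global_rsf.csv"))
      results$survshap_global <- agg_global
    }
  })

  run_stage("cph", function() {
    if (!config$fit_cph_comparison) return(invisible(NULL))
    union_feats <- sort(unique(unlist(lapply(
      results$shap_aggregates,
      function(agg) head(agg$ranking$feature, 5L)))))
    jsonlite::write_json(union_feats,
                         art("cph_union_features",
                             "cph_union_features.json"), digits = NA)
    train <- results$train
    plan <- results$plan
    cph_models <- list()
    for (r in seq_len(plan$repeats)) {
      for (f in seq_len(plan$k)) {
        tr <- train[plan$assignment[, r] != f, , drop = FALSE]
        model <- suppressWarnings(fit_cph(tr, union_feats))
        model$model_id <- sprintf("cph_r%02d_f%02d", r, f)
        cph_models[[length(cph_models) + 1L]] <- model
      }
    }
    perf <- evaluate_ensemble(cph_models, results$holdout)
    write_performance_summary(
      perf, csv_path = art("cph_performance", "cph_performance.csv"))
    full_cph <- suppressWarnings(fit_cph(train, union_feats))
    co <- summary(full_cph$fit)$coefficients
    write.csv(data.frame(term = rownames(co), co, row.names = NULL,
                         check.names = FALSE),
              art("cph_coefficients", "cph_coefficients.csv"),
              row.names = FALSE)
    results$cph_performance <- perf
    results$cph_union_features <- union_feats
  })

  run_stage("report", function() {
    overall <- results$performance$summary
    jsonlite::write_json(
      list(censoring = results$censoring,
           holdout_c_index = overall[overall$subset == "overall", ],
           cph_c_index = if (!is.null(results$cph_performance))
             results$cph_performance$summary[
               results$cph_performance$summary$subset == "overall", ]),
      art("report", "report.json"), auto_unbox = TRUE, digits = NA)
  })

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 results = as.list(results)))
}
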