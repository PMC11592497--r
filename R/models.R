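# Survival risk models behind a uniform prediction contract -------------------
#
# Three model families share one contract: `predict_risk()` returns one
# finite real per observation with higher values meaning higher mortality
# risk; families with the `survival_function` capability additionally
# expose `predict_survival()` over a time grid. Risk conventions: RSF uses
# the ensemble cumulative hazard summed over the event-time grid, boosted
# Cox and CPH use the linear predictor (log relative hazard).

RSF_BOUNDS <- list(
  num_trees = c(100, 1000), max_depth = c(1, 40), mtry = c(2, 9),
  min_node_size = c(1, 20), sample_fraction = c(0.3, 1)
)
BOOSTED_COX_BOUNDS <- list(
  max_depth = c(1, 40), learning_rate = c(0.001, 0.2),
  subsample = c(0.3, 1), colsample_bytree = c(0.3, 1),
  min_child_weight = c(0, 10)
)

#' Random survival forest configuration
#'
#' Defaults are a tuned setting appropriate for cohorts of this scale; all
#' values are validated against the search-space bounds.
#'
#' @param num_trees,max_depth,mtry,min_node_size,sample_fraction Forest
#'   hyperparameters.
#' @return A list of class `rsf_config`.
#' @export
rsf_config <- function(num_trees = 100L, max_depth = 40L, mtry = 2L,
                       min_node_size = 20L, sample_fraction = 0.63) {
  cfg <- list(num_trees = num_trees, max_depth = max_depth, mtry = mtry,
              min_node_size = min_node_size,
              sample_fraction = sample_fraction)
  for (p in c("num_trees", "max_depth", "mtry", "min_node_size")) {
    assert_number(cfg[[p]], p, RSF_BOUNDS[[p]][1], RSF_BOUNDS[[p]][2],
                  integer = TRUE)
  }
  assert_number(cfg$sample_fraction, "sample_fraction",
                RSF_BOUNDS$sample_fraction[1], RSF_BOUNDS$sample_fraction[2])
  structure(cfg, class = "rsf_config")
}

#' Gradient-boosted Cox configuration
#'
#' Cox partial-likelihood boosting; `num_rounds` is an upper bound when
#' early stopping is active (the realised round count is logged in the
#' fitted model's metadata).
#'
#' @param max_depth,learning_rate,subsample,colsample_bytree,min_child_weight
#'   Booster hyperparameters.
#' @param num_rounds Maximum boosting rounds.
#' @param early_stopping_rounds Stop when the validation loss has not
#'   improved for this many rounds (default 500); `NULL` disables early
#'   stopping.
#' @return A list of class `boosted_cox_config`.
#' @export
boosted_cox_config <- function(max_depth = 5L, learning_rate = 0.11,
                               subsample = 0.5, colsample_bytree = 0.8,
                               min_child_weight = 1, num_rounds = 5000L,
                               early_stopping_rounds = 500L) {
  cfg <- list(max_depth = max_depth, learning_rate = learning_rate,
              subsample = subsample, colsample_bytree = colsample_bytree,
              min_child_weight = min_child_weight,
              num_rounds = num_rounds,
              early_stopping_rounds = early_stopping_rounds)
  assert_number(max_depth, "max_depth", BOOSTED_COX_BOUNDS$max_depth[1],
                BOOSTED_COX_BOUNDS$max_depth[2], integer = TRUE)
  assert_number(learning_rate, "learning_rate", 0,
                BOOSTED_COX_BOUNDS$learning_rate[2], open_lower = TRUE)
  if (learning_rate < BOOSTED_COX_BOUNDS$learning_rate[1]) {
    stop_field("learning_rate", "must be at least 0.001")
  }
  assert_number(subsample, "subsample", 0.3, 1)
  assert_number(colsample_bytree, "colsample_bytree", 0.3, 1)
  assert_number(min_child_weight, "min_child_weight", 0, 10)
  assert_number(num_rounds, "num_rounds", lower = 0, integer = TRUE)
  if (!is.null(early_stopping_rounds)) {
    assert_number(early_stopping_rounds, "early_stopping_rounds", lower = 1,
                  integer = TRUE)
  }
  structure(cfg, class = "boosted_cox_config")
}

new_risk_model <- function(kind, fit, capabilities, features, config, seed,
                           meta = list()) {
  structure(list(kind = kind, fit = fit, capabilities = capabilities,
                 features = features, config = config, seed = seed,
                 meta = meta,
                 model_id = sprintf("%s_seed%s", kind, seed)),
            class = c(paste0(kind, "_model"), "risk_model"))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %s> %d features; capabilities: %s\n", x$kind,
              length(x$features), paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

check_train <- function(train, min_events = 2L) {
  stopifnot(all(c("time", "status") %in% names(train)))
  if (sum(train$status == 1L) < min_events) {
    stop(sprintf("training data must contain at least %d events",
                 min_events), call. = FALSE)
  }
  invisible(train)
}

model_frame <- function(data, features) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    stop(sprintf("newdata lacks feature(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  as.data.frame(data)[features]
}

#' Fit a random survival forest
#'
#' @param train An `engineered_dataset` (predictors plus `time`/`status`).
#' @param config An [rsf_config()].
#' @param seed Integer seed.
#' @param features Predictor columns (default: the engineered predictors
#'   present in `train`).
#' @return A `risk_model` with capabilities `risk` and `survival_function`.
#'   Risk is the ensemble cumulative hazard summed over the event-time
#'   grid (higher = worse).
#' @export
fit_rsf <- function(train, config = rsf_config(), seed = 1L,
                    features = NULL) {
  check_train(train)
  if (is.null(features)) {
    features <- intersect(ENGINEERED_PREDICTORS, names(train))
  }
  df <- cbind(model_frame(train, features),
              time = train$time, status = as.integer(train$status))
  fit <- ranger::ranger(
    dependent.variable.name = "time", status.variable.name = "status",
    data = df, num.trees = config$num_trees,
    max.depth = config$max_depth,
    mtry = min(config$mtry, length(features)),
    min.node.size = config$min_node_size,
    sample.fraction = config$sample_fraction,
    seed = as.integer(seed), num.threads = 1L, verbose = FALSE
  )
  # per-leaf cumulative-hazard sums: risk prediction then only needs the
  # (cheap) terminal-node lookup instead of the full CHF aggregation
  leaf_chf_sum <- lapply(fit$forest$chf, function(tree) {
    vapply(tree, function(v) if (length(v)) sum(v) else 0, numeric(1))
  })
  new_risk_model("rsf", fit, c("risk", "survival_function"), features,
                 config, seed,
                 meta = list(unique_death_times = fit$unique.death.times,
                             leaf_chf_sum = leaf_chf_sum))
}

#' Fit a gradient-boosted Cox model
#'
#' Labels follow the Cox-boosting convention: positive follow-up times are
#' events, negated times are censored. Risk predictions are the boosted
#' linear predictor (log relative hazard).
#'
#' @param train An `engineered_dataset`.
#' @param config A [boosted_cox_config()].
#' @param validation Engineered rows used as the early-stopping validation
#'   set; required when `early_stopping_rounds` is set.
#' @param seed Integer seed.
#' @param features Predictor columns.
#' @return A `risk_model` with capability `risk`; `meta$num_rounds_used`
#'   logs the realised boosting rounds.
#' @export
fit_boosted_cox <- function(train, config = boosted_cox_config(),
                            validation = NULL, seed = 1L, features = NULL) {
  check_train(train)
  if (is.null(features)) {
    features <- intersect(ENGINEERED_PREDICTORS, names(train))
  }
  use_es <- !is.null(config$early_stopping_rounds) && config$num_rounds > 0L
  if (use_es && (is.null(validation) || nrow(validation) == 0L)) {
    stop("early stopping requested but no validation data supplied",
         call. = FALSE)
  }
  trm <- stats::terms(stats::reformulate(features))
  mf <- model_frame(train, features)
  xlev <- lapply(mf[vapply(mf, is.factor, logical(1))], levels)
  encode <- function(data) {
    mm <- model.matrix(trm, data = model_frame(data, features), xlev = xlev)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  cox_label <- function(data) ifelse(data$status == 1L, data$time,
                                     -data$time)
  meta <- list(num_rounds_used = 0L)
  fit <- NULL
  if (config$num_rounds > 0L) {
    dtrain <- xgboost::xgb.DMatrix(encode(train), label = cox_label(train))
    params <- list(objective = "survival:cox",
                   eta = config$learning_rate,
                   max_depth = config$max_depth,
                   subsample = config$subsample,
                   colsample_bytree = config$colsample_bytree,
                   min_child_weight = config$min_child_weight,
                   nthread = 1L, seed = as.integer(seed))
    if (use_es) {
      dval <- xgboost::xgb.DMatrix(encode(validation),
                                   label = cox_label(validation))
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$num_rounds,
                                evals = list(validation = dval),
                                early_stopping_rounds =
                                  config$early_stopping_rounds,
                                verbose = 0)
      best <- suppressWarnings(
        as.integer(xgboost::xgb.attr(fit, "best_iteration")))
      meta$num_rounds_used <- if (length(best) && !is.na(best)) best else
        config$num_rounds
    } else {
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$num_rounds, verbose = 0)
      meta$num_rounds_used <- config$num_rounds
    }
  }
  m <- new_risk_model("boosted_cox", fit, "risk", features, config, seed,
                      meta = meta)
  m$encode <- encode
  m
}

#' Fit a Cox proportional hazards model
#'
#' Breslow tie handling throughout; risk is the linear predictor relative
#' to zero covariates, and the Breslow baseline cumulative hazard provides
#' the survival-function capability.
#'
#' @param train An `engineered_dataset`.
#' @param features Predictor subset to use (e.g. the union of the top-5
#'   features of the ML families).
#' @return A `risk_model` with capabilities `risk` and `survival_function`.
#' @export
fit_cph <- function(train, features) {
  check_train(train)
  missing_cols <- setdiff(features, names(train))
  if (length(missing_cols)) {
    stop(sprintf("features not in training data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n_events <- sum(train$status == 1L)
  if (n_events < length(features)) {
    warning(sprintf("only %d events for %d features; estimates may be
                    unstable", n_events, length(features)), call. = FALSE)
  }
  df <- cbind(model_frame(train, features),
              time = train$time, status = as.integer(train$status))
  fit <- survival::coxph(
    survival::Surv(time, status) ~ ., data = df, ties = "breslow",
    model = TRUE, x = FALSE)
  if (anyNA(coef(fit))) {
    stop("degenerate (collinear) design: Cox coefficients not estimable",
         call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  new_risk_model("cph", fit, c("risk", "survival_function"), features,
                 config = list(features = features), seed = NA_integer_,
                 meta = list(baseline_hazard = bh))
}

#' Predict mortality risk scores
#'
#' @param model A `risk_model`.
#' @param newdata Data with the model's feature columns.
#' @return A numeric vector, one finite risk per row (higher = higher
#'   mortality risk).
#' @export
predict_risk <- function(model, newdata) UseMethod("predict_risk")

rsf_terminal_nodes <- function(model, newdata) {
  predict(model$fit, data = model_frame(newdata, model$features),
          type = "terminalNodes", num.threads = 1L,
          verbose = FALSE)$predictions
}

# Process rows in blocks so the (rows x trees) terminal-node matrix stays
# small regardless of the hybrid-batch size SHAP estimators produce.
rsf_row_blocks <- function(n, num_trees, target = 5e6) {
  block <- max(1000L, as.integer(ceiling(target / max(1, num_trees))))
  split(seq_len(n), ceiling(seq_len(n) / block))
}

#' @export
predict_risk.rsf_model <- function(model, newdata) {
  lrs <- model$meta$leaf_chf_sum
  out <- numeric(nrow(newdata))
  for (rows in rsf_row_blocks(nrow(newdata), length(lrs))) {
    tn <- rsf_terminal_nodes(model, newdata[rows, , drop = FALSE])
    acc <- numeric(length(rows))
    for (t in seq_along(lrs)) acc <- acc + lrs[[t]][tn[, t] + 1L]
    out[rows] <- acc / length(lrs)
  }
  unname(out)
}

#' @export
predict_risk.boosted_cox_model <- function(model, newdata) {
  if (is.null(model$fit)) return(rep(0, nrow(newdata)))
  dm <- xgboost::xgb.DMatrix(model$encode(newdata))
  n_used <- model$meta$num_rounds_used
  unname(predict(model$fit, dm, outputmargin = TRUE,
                 iterationrange = c(1L, as.integer(n_used))))
}

#' @export
predict_risk.cph_model <- function(model, newdata) {
  unname(predict(model$fit,
                 newdata = model_frame(newdata, model$features),
                 type = "lp", reference = "zero"))
}

#' Predict survival functions over a time grid
#'
#' @param model A `risk_model` with the `survival_function` capability.
#' @param newdata Data with the model's feature columns.
#' @param times Non-decreasing evaluation times.
#' @return A matrix (`nrow(newdata)` x `length(times)`) of survival
#'   probabilities, non-increasing along each row with values in `[0, 1]`
#'   and `S(0) = 1`.
#' @export
predict_survival <- function(model, newdata, times) {
  UseMethod("predict_survival")
}

# Right-continuous step-function lookup: value at the last grid time <= t.
step_eval <- function(grid_times, values, times) {
  idx <- findInterval(times, grid_times)
  cbind(1, values)[, idx + 1L, drop = FALSE]
}

#' @export
predict_survival.rsf_model <- function(model, newdata, times) {
  # ensemble survival = exp(-mean tree CHF); the CHF is a step function
  # over the unique death times, evaluated here only at the requested grid
  udt <- model$fit$unique.death.times
  idx <- findInterval(times, udt)
  chf <- model$fit$forest$chf
  pos <- which(idx > 0L)
  # per-tree node-by-time matrices, shared across row blocks
  Vs <- lapply(chf, function(tree) {
    V <- matrix(0, length(tree), length(times))
    if (length(pos)) {
      nz <- which(lengths(tree) > 0L)
      vm <- vapply(tree[nz], function(v) v[idx[pos]],
                   numeric(length(pos)))
      V[nz, pos] <- if (length(pos) == 1L) vm else t(vm)
    }
    V
  })
  out <- matrix(0, nrow(newdata), length(times))
  for (rows in rsf_row_blocks(nrow(newdata), length(chf))) {
    tn <- rsf_terminal_nodes(model, newdata[rows, , drop = FALSE])
    H <- matrix(0, length(rows), length(times))
    for (t in seq_along(Vs)) {
      H <- H + Vs[[t]][tn[, t] + 1L, , drop = FALSE]
    }
    out[rows, ] <- H
  }
  exp(-out / length(chf))
}

#' @export
predict_survival.boosted_cox_model <- function(model, newdata, times) {
  stop("boosted Cox models expose risk scores only (no survival function)",
       call. = FALSE)
}

#' @export
predict_survival.cph_model <- function(model, newdata, times) {
  bh <- model$meta$baseline_hazard
  lp <- predict_risk(model, newdata)
  # cumulative hazard is 0 before the first event time, i.e. S = 1 there
  H0 <- c(0, bh$hazard)[findInterval(times, bh$time) + 1L]
  out <- exp(-outer(exp(lp), H0))
  dimnames(out) <- NULL
  out
}

#' Capabilities of a risk model
#' @param model A `risk_model`.
#' @return Character vector of capabilities.
#' @export
model_capabilities <- function(model) model$capabilities

#' Fitted-model metadata as JSON
#'
#' Records kind, configuration, seed and realised round counts.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model_meta_json <- function(model, path) {
  meta <- list(kind = model$kind, model_id = model$model_id,
               config = unclass(model$config), seed = model$seed,
               num_rounds_used = model$meta$num_rounds_used)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
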