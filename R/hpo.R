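# Bayesian hyperparameter optimisation ----------------------------------------
#
# Gaussian-process surrogate (Matern-5/2 kernel on the unit cube) with an
# upper-confidence-bound acquisition. The optimiser is initialised from a
# pre-computed parameter grid and then proposes points anywhere inside the
# declared bounds; integer parameters stay integral throughout.

#' Hyperparameter search space
#'
#' @param params Named list; each element is a list with `bounds`
#'   (`c(lower, upper)`), `integer` flag, and `grid` (the initial sampling
#'   pool inside the bounds).
#' @return An object of class `search_space`.
#' @export
search_space <- function(params) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (length(p$bounds) != 2L || p$bounds[1] > p$bounds[2]) {
      stop_field(nm, "bounds must be c(lower, upper)")
    }
    if (length(p$grid) == 0L || any(p$grid < p$bounds[1]) ||
        any(p$grid > p$bounds[2])) {
      stop_field(nm, "grid points must lie inside the bounds")
    }
  }
  structure(params, class = "search_space")
}

#' Default search spaces for the two ML families
#'
#' Grids (minimum/maximum/step) form the initialisation pool; bounds
#' constrain every later proposal.
#'
#' @return A [search_space()].
#' @export
rsf_search_space <- function() {
  search_space(list(
    num_trees = list(bounds = c(100, 1000), integer = TRUE,
                     grid = seq(500, 1000, by = 500)),
    max_depth = list(bounds = c(1, 40), integer = TRUE,
                     grid = seq(1, 9, by = 4)),
    mtry = list(bounds = c(2, 9), integer = TRUE, grid = seq(2, 6, by = 2)),
    min_node_size = list(bounds = c(1, 20), integer = TRUE,
                         grid = seq(1, 9, by = 4)),
    sample_fraction = list(bounds = c(0.3, 1), integer = FALSE,
                           grid = seq(0.5, 0.8, by = 0.3))
  ))
}

#' @rdname rsf_search_space
#' @export
boosted_cox_search_space <- function() {
  search_space(list(
    colsample_bytree = list(bounds = c(0.3, 1), integer = FALSE,
                            grid = seq(0.5, 0.8, by = 0.3)),
    learning_rate = list(bounds = c(0.001, 0.2), integer = FALSE,
                         grid = seq(0.01, 0.11, by = 0.05)),
    max_depth = list(bounds = c(1, 40), integer = TRUE,
                     grid = seq(1, 9, by = 4)),
    min_child_weight = list(bounds = c(0, 10), integer = FALSE,
                            grid = seq(1, 9, by = 4)),
    subsample = list(bounds = c(0.3, 1), integer = FALSE,
                     grid = seq(0.5, 0.8, by = 0.3))
  ))
}

#' Bayesian-optimisation configuration
#'
#' @param kappa Exploration weight of the upper confidence bound
#'   (default 3.5).
#' @param n_sampling_runs Surrogate-guided evaluations after
#'   initialisation (default 128).
#' @param n_init Random initial settings drawn from the grid pool
#'   (default 50).
#' @param seed Integer seed.
#' @return An object of class `bayes_opt_config`.
#' @export
bayes_opt_config <- function(kappa = 3.5, n_sampling_runs = 128L,
                             n_init = 50L, seed = 1L) {
  assert_number(kappa, "kappa", lower = 0, open_lower = TRUE)
  assert_number(n_sampling_runs, "n_sampling_runs", lower = 0,
                integer = TRUE)
  assert_number(n_init, "n_init", lower = 1, integer = TRUE)
  structure(list(kappa = kappa, n_sampling_runs = as.integer(n_sampling_runs),
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "bayes_opt_config")
}

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

unit_dist <- function(A, B) {
  # Euclidean distances between rows of two unit-scaled matrices
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

gp_posterior <- function(U, y, Ucand, lengthscale, nugget = 1e-6) {
  s2 <- max(var(y), 1e-12)
  K <- s2 * matern52(unit_dist(U, U) / lengthscale) +
    diag(nugget * s2 + 1e-10, nrow(U))
  Ks <- s2 * matern52(unit_dist(Ucand, U) / lengthscale)
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, y - mean(y), transpose = TRUE))
  mu <- mean(y) + drop(Ks %*% alpha)
  V <- backsolve(L, t(Ks), transpose = TRUE)
  var_cand <- pmax(s2 - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var_cand))
}

to_unit <- function(X, space) {
  U <- X
  for (j in seq_along(space)) {
    b <- space[[j]]$bounds
    U[, j] <- if (b[2] > b[1]) (X[, j] - b[1]) / (b[2] - b[1]) else 0.5
  }
  U
}

setting_row <- function(x, space) {
  s <- as.list(x)
  names(s) <- names(space)
  for (nm in names(space)) if (space[[nm]]$integer) s[[nm]] <- round(s[[nm]])
  s
}

#' Bayesian optimisation of a tuning objective
#'
#' Maximises `objective` (e.g. mean stratified 3-fold CV C-index) over the
#' search space: `n_init` settings sampled from the grid pool, then
#' `n_sampling_runs` proposals maximising the upper confidence bound
#' `mu + kappa * sd` of a Gaussian-process surrogate over random candidate
#' settings inside the bounds. A failing objective marks the point failed
#' and optimisation continues. Deterministic given `config$seed`.
#'
#' @param objective Function taking a named setting list, returning a
#'   scalar to maximise.
#' @param space A [search_space()].
#' @param config A [bayes_opt_config()].
#' @param n_candidates Random candidate settings scored per BO iteration.
#' @return A list of class `tuning_result`: `best_setting`, `best_value`,
#'   and the full evaluation `trace` data frame.
#' @export
bayesian_optimize <- function(objective, space, config = bayes_opt_config(),
                              n_candidates = 256L) {
  stopifnot(inherits(space, "search_space"))
  d <- length(space)
  pool <- as.matrix(expand.grid(lapply(space, `[[`, "grid"),
                                KEEP.OUT.ATTRS = FALSE))
  draw_uniform <- function(n) {
    X <- vapply(space, function(p) {
      x <- runif(n, p$bounds[1], p$bounds[2])
      if (p$integer) round(x) else x
    }, numeric(n))
    matrix(X, nrow = n, dimnames = list(NULL, names(space)))
  }

  with_seed(config$seed, {
    n0 <- min(config$n_init, nrow(pool))
    X <- pool[sample.int(nrow(pool), n0), , drop = FALSE]
    if (config$n_init > n0) {
      X <- rbind(X, draw_uniform(config$n_init - n0))
    }
    evaluate <- function(x) {
      tryCatch(as.numeric(objective(setting_row(x, space))),
               error = function(e) NA_real_)
    }
    y <- apply(X, 1L, evaluate)
    phase <- rep("init", nrow(X))
    for (it in seq_len(config$n_sampling_runs)) {
      ok <- !is.na(y)
      if (sum(ok) >= 2L && var(y[ok]) > 0) {
        cand <- draw_uniform(n_candidates)
        seen <- apply(X, 1L, paste, collapse = "\r")
        new <- !(apply(cand, 1L, paste, collapse = "\r") %in% seen)
        if (!any(new)) cand <- draw_uniform(n_candidates) else
          cand <- cand[new, , drop = FALSE]
        post <- gp_posterior(to_unit(X[ok, , drop = FALSE], space), y[ok],
                             to_unit(cand, space), lengthscale = 0.3)
        x_next <- cand[which.max(post$mean + config$kappa * post$sd), ]
      } else {
        x_next <- draw_uniform(1L)[1L, ]
      }
      X <- rbind(X, x_next)
      y <- c(y, evaluate(x_next))
      phase <- c(phase, "bo")
    }
  })

  trace <- data.frame(iteration = seq_len(nrow(X)), phase = phase,
                      as.data.frame(X), objective = y, failed = is.na(y),
                      stringsAsFactors = FALSE)
  if (all(is.na(y))) stop("all objective evaluations failed", call. = FALSE)
  best <- which.max(ifelse(is.na(y), -Inf, y))
  structure(list(best_setting = setting_row(X[best, ], space),
                 best_value = y[best], trace = trace),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> best objective:", format(x$best_value), "\n")
  str(x$best_setting, give.attr = FALSE)
  invisible(x)
}

#' Build a cross-validated tuning objective
#'
#' Returns the function mapping a hyperparameter setting to the mean
#' C-index over fixed stratified CV folds, shared across model families so
#' both are tuned on identical folds.
#'
#' @param data Engineered training data.
#' @param fold_ids Integer fold assignment per row (e.g. one column of a
#'   [repeated_cv_folds()] plan).
#' @param family `"rsf"` or `"boosted_cox"`.
#' @param seed Integer seed forwarded to each fit.
#' @return A function `setting -> mean CV C-index`.
#' @export
make_cv_objective <- function(data, fold_ids, family = c("rsf",
                                                         "boosted_cox"),
                              seed = 1L) {
  family <- match.arg(family)
  folds <- sort(unique(fold_ids))
  function(setting) {
    cis <- vapply(folds, function(f) {
      tr <- data[fold_ids != f, , drop = FALSE]
      te <- data[fold_ids == f, , drop = FALSE]
      model <- if (family == "rsf") {
        fit_rsf(tr, config = do.call(rsf_config, setting), seed = seed)
      } else {
        fit_boosted_cox(tr, config = do.call(boosted_cox_config, setting),
                        validation = te, seed = seed)
      }
      harrell_c_index(te$time, te$status, predict_risk(model, te))
    }, numeric(1))
    mean(cis)
  }
}

#' Write a tuning trace as CSV and the best setting as JSON
#'
#' @param result A `tuning_result`.
#' @param trace_csv,best_json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_tuning_result <- function(result, trace_csv = NULL, best_json = NULL) {
  if (!is.null(trace_csv)) write.csv(result$trace, trace_csv,
                                     row.names = FALSE)
  if (!is.null(best_json)) {
    jsonlite::write_json(list(best_setting = result$best_setting,
                              best_value = result$best_value),
                         best_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(trace_csv, best_json))
}
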