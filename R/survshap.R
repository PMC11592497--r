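# Time-dependent Shapley explanations of survival functions -------------------
#
# SurvSHAP(t) attributes the predicted survival function to features: at
# every grid time t, per-feature curves sum (with the background-average
# survival as base) to the model's predicted S(t | x). Global curves
# average over observations; aggregated-global curves additionally average
# over repeated-CV models.

#' Time grid from training follow-up times
#'
#' Unique event times of the training fold, thinned to at most
#' `max_points` by quantile thinning.
#'
#' @param time,status Training outcome vectors.
#' @param max_points Cap on the grid size (default 200).
#' @return Sorted numeric grid.
#' @export
time_grid <- function(time, status, max_points = 200L) {
  ts <- sort(unique(time[status == 1L]))
  if (length(ts) == 0L) stop("no event times to build a grid from",
                             call. = FALSE)
  if (length(ts) > max_points) {
    ts <- unique(quantile(ts, probs = seq(0, 1, length.out = max_points),
                          type = 1))
  }
  unname(ts)
}

#' SurvSHAP(t) attribution curves
#'
#' Per-observation, per-feature attribution curves of the predicted
#' survival function over a shared time grid. At every grid time the
#' attributions of an observation sum to `S_model(t | x) - S_bar(t)`,
#' where `S_bar` is the background-average survival curve.
#'
#' @param model A `risk_model` exposing the `survival_function`
#'   capability (e.g. RSF or CPH; boosted Cox errors).
#' @param X Observations to explain.
#' @param background Background dataset (the model's training fold).
#' @param grid Evaluation times (default: event-time grid of the
#'   background via [time_grid()], when outcome columns are present).
#' @param method `"sampling"` or `"exact"` (p <= 10).
#' @param n_perm Permutations for the sampling estimator.
#' @param seed Integer seed.
#' @return An object of class `survshap_curves`: `values` array
#'   (n x p x m), `grid`, `base_curve`, `pred_curves`, `features`,
#'   `model_id`.
#' @export
survshap_curves <- function(model, X, background, grid = NULL,
                            method = c("sampling", "exact"), n_perm = 64L,
                            seed = 1L) {
  method <- match.arg(method)
  if (!("survival_function" %in% model_capabilities(model))) {
    stop(sprintf("model '%s' does not expose a survival function; SurvSHAP(t) requires one",
                 model$kind), call. = FALSE)
  }
  if (is.null(grid)) {
    if (is.null(background$time) || is.null(background$status)) {
      stop("supply a time grid or a background with outcome columns",
           call. = FALSE)
    }
    grid <- time_grid(background$time, background$status)
  }
  grid <- sort(unique(grid))
  feats <- model$features
  Xf <- model_frame(X, feats)
  bgf <- model_frame(background, feats)
  vf <- function(df) predict_survival(model, df, grid)
  est <- shapley_estimate(vf, Xf, bgf, method, n_perm, seed)
  dimnames(est$values) <- list(NULL, feats, NULL)
  structure(list(values = est$values, grid = grid, base_curve = est$base,
                 pred_curves = est$pred, features = feats,
                 model_id = model$model_id, method = method),
            class = "survshap_curves")
}

#' @export
print.survshap_curves <- function(x, ...) {
  cat(sprintf("<survshap_curves> %d observations x %d features x %d times (model %s)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$model_id))
  invisible(x)
}

#' Global SurvSHAP(t) curves
#'
#' Averages attribution curves over observations, yielding one curve per
#' feature.
#'
#' @param curves A `survshap_curves`.
#' @return An object of class `global_survshap_curves`: `values`
#'   (p x m matrix), `grid`, `base_curve`, `n`, `model_id`.
#' @export
global_survshap <- function(curves) {
  stopifnot(inherits(curves, "survshap_curves"))
  n <- dim(curves$values)[1]
  if (n < 1L) stop("no observations to average over", call. = FALSE)
  values <- apply(curves$values, c(2, 3), mean)
  structure(list(values = values, grid = curves$grid,
                 base_curve = curves$base_curve, n = n,
                 features = curves$features, model_id = curves$model_id),
            class = "global_survshap_curves")
}

#' Aggregate global SurvSHAP(t) curves across repeated-CV models
#'
#' Element-wise mean of per-model global curves on a shared grid.
#'
#' @param globals List of `global_survshap_curves` sharing features and
#'   grid.
#' @return An object of class `global_survshap_curves` with `l` models.
#' @export
aggregate_survshap_over_models <- function(globals) {
  stopifnot(length(globals) >= 1L)
  g1 <- globals[[1]]
  for (g in globals) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        !isTRUE(all.equal(g$grid, g1$grid))) {
      stop("global curves must share features and time grid", call. = FALSE)
    }
  }
  values <- Reduce(`+`, lapply(globals, `[[`, "values")) / length(globals)
  structure(list(values = values, grid = g1$grid,
                 base_curve = Reduce(`+`, lapply(globals, `[[`,
                                                 "base_curve")) /
                   length(globals),
                 l = length(globals), features = g1$features,
                 model_id = sprintf("aggregate_of_%d", length(globals))),
            class = "global_survshap_curves")
}

#' Feature importance from SurvSHAP(t) curves
#'
#' Mean absolute attribution over observations and grid times, the
#' time-dependent analogue of mean-|phi| importance.
#'
#' @param curves A `survshap_curves`.
#' @return A data frame `feature`, `mean_abs_phi`.
#' @export
survshap_importance <- function(curves) {
  imp <- data.frame(feature = curves$features,
                    mean_abs_phi = apply(abs(curves$values), 2, mean),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_abs_phi, imp$feature), ]
  rownames(imp) <- NULL
  imp
}

#' Write SurvSHAP(t) curves in long CSV format
#'
#' Global curves: one row per (feature, t). Per-observation curves: one
#' row per (observation, feature, t).
#'
#' @param curves A `survshap_curves` or `global_survshap_curves`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_survshap_csv <- function(curves, path) {
  if (inherits(curves, "global_survshap_curves")) {
    long <- data.frame(
      feature = rep(curves$features, times = length(curves$grid)),
      t = rep(curves$grid, each = length(curves$features)),
      value = as.vector(curves$values), model_id = curves$model_id,
      stringsAsFactors = FALSE)
  } else {
    d <- dim(curves$values)
    long <- data.frame(
      observation = rep(seq_len(d[1]), times = d[2] * d[3]),
      feature = rep(rep(curves$features, each = d[1]), times = d[3]),
      t = rep(curves$grid, each = d[1] * d[2]),
      value = as.vector(curves$values), model_id = curves$model_id,
      stringsAsFactors = FALSE)
  }
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
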