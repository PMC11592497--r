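# Shapley attributions for risk models -----------------------------------------
#
# Two estimators drive all attribution outputs: exact subset enumeration
# (cost 2^p, allowed for p <= 10) and antithetic permutation sampling.
# Both satisfy the efficiency/additivity identity by construction: for
# every observation, base value + sum of attributions equals the model
# prediction (up to floating-point error). Coalition values are model
# predictions on hybrid rows averaged over a background dataset, which
# should be drawn from the explained model's training fold.

# Shared estimator for (possibly vector-valued) prediction functions.
# `vf(data)` must return an (nrow(data) x m) numeric matrix.
shapley_estimate <- function(vf, X, background, method, n_perm, seed,
                             max_rows = 250000L) {
  p <- ncol(X)
  n <- nrow(X)
  n_bg <- nrow(background)
  if (n_bg == 0L) stop("background data must be non-empty", call. = FALSE)
  base <- colMeans(as_matrix_pred(vf(background)))
  pred <- as_matrix_pred(vf(X))
  m <- length(base)
  values <- array(0, dim = c(n, p, m))

  if (method == "exact") {
    if (p > 10L) {
      stop("exact enumeration is limited to p <= 10 features; use method = 'sampling'",
           call. = FALSE)
    }
    masks <- 0:(2^p - 1L)
    bits <- 2^(0:(p - 1L))
    mask_mat <- t(vapply(masks, function(msk) bitwAnd(msk, bits) > 0,
                         logical(p)))
    popcount <- rowSums(mask_mat)
    interior <- which(popcount > 0 & popcount < p)  # row indices into masks
    # weight |S|! (p - |S| - 1)! / p! ; only masks with |S| < p are used
    shap_w <- ifelse(popcount < p,
                     factorial(popcount) * factorial(pmax(p - popcount - 1L,
                                                          0L)) /
                       factorial(p), 0)
    obs_per_chunk <- max(1L, floor(max_rows / max(1L, length(interior) *
                                                    n_bg)))
    for (i0 in seq(1L, n, by = obs_per_chunk)) {
      idx <- i0:min(n, i0 + obs_per_chunk - 1L)
      v_int <- coalition_values(vf, X[idx, , drop = FALSE], background,
                                mask_mat[interior, , drop = FALSE])
      for (ii in seq_along(idx)) {
        v_all <- matrix(rep(base, each = length(masks)),
                        nrow = length(masks), ncol = m)
        v_all[interior, ] <- v_int[(ii - 1L) * length(interior) +
                                     seq_along(interior), , drop = FALSE]
        v_all[length(masks), ] <- pred[idx[ii], ]
        for (j in seq_len(p)) {
          without <- which(!mask_mat[, j])          # masks lacking feature j
          with_j <- without + bits[j]               # same masks plus j
          diffs <- v_all[with_j, , drop = FALSE] -
            v_all[without, , drop = FALSE]
          values[idx[ii], j, ] <- colSums(diffs * shap_w[without])
        }
      }
    }
  } else {
    if (n_perm < 2L) stop_field("n_perm", "must be at least 2")
    if (n_perm %% 2L != 0L) n_perm <- n_perm + 1L  # antithetic pairs
    half <- n_perm / 2L
    perms <- with_seed(seed, {
      lapply(seq_len(n), function(i) {
        fwd <- replicate(half, sample.int(p), simplify = FALSE)
        do.call(rbind, c(fwd, lapply(fwd, rev)))
      })
    })
    coal_per_obs <- n_perm * (p - 1L)
    obs_per_chunk <- max(1L, floor(max_rows / max(1L, coal_per_obs * n_bg)))
    for (i0 in seq(1L, n, by = obs_per_chunk)) {
      idx <- i0:min(n, i0 + obs_per_chunk - 1L)
      nc <- length(idx)
      # coalition order: (obs, perm, prefix length s = 1..p-1)
      C <- nc * coal_per_obs
      mask <- matrix(FALSE, nrow = C, ncol = p)
      s_vec <- rep(seq_len(p - 1L), times = nc * n_perm)
      for (j in seq_len(p)) {
        rank_j <- unlist(lapply(idx, function(i) {
          rep(apply(perms[[i]], 1L, function(pp) which(pp == j)),
              each = p - 1L)
        }))
        mask[, j] <- rank_j <= s_vec
      }
      v <- coalition_values(vf, X[idx, , drop = FALSE], background, mask,
                            per_obs_masks = coal_per_obs)
      for (ii in seq_len(nc)) {
        i <- idx[ii]
        acc <- matrix(0, nrow = p, ncol = m)
        for (q in seq_len(n_perm)) {
          off <- (ii - 1L) * coal_per_obs + (q - 1L) * (p - 1L)
          vseq <- rbind(matrix(base, nrow = 1L),
                        v[off + seq_len(p - 1L), , drop = FALSE],
                        matrix(pred[i, ], nrow = 1L))
          inc <- vseq[-1L, , drop = FALSE] - vseq[-nrow(vseq), , drop = FALSE]
          acc[perms[[i]][q, ], ] <- acc[perms[[i]][q, ], ] + inc
        }
        values[i, , ] <- acc / n_perm
      }
    }
  }
  list(values = values, base = base, pred = pred)
}

as_matrix_pred <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Coalition values: mean model output over background rows with coalition
# features replaced by the explained observation's values.
# `mask` has one row per coalition; coalitions are grouped per observation
# (either `nrow(mask)` rows all for a chunk laid out per obs via
# `per_obs_masks`, or the same mask set reused for every observation).
coalition_values <- function(vf, X, background, mask, per_obs_masks = NULL) {
  n <- nrow(X)
  n_bg <- nrow(background)
  p <- ncol(X)
  if (is.null(per_obs_masks)) {
    # same masks for every observation: replicate
    n_mask <- nrow(mask)
    coal_obs <- rep(seq_len(n), each = n_mask)
    mask_idx <- rep(seq_len(n_mask), times = n)
    mask_big <- mask[mask_idx, , drop = FALSE]
  } else {
    stopifnot(nrow(mask) == n * per_obs_masks)
    coal_obs <- rep(seq_len(n), each = per_obs_masks)
    mask_big <- mask
  }
  C <- length(coal_obs)
  coal_of_row <- rep(seq_len(C), each = n_bg)
  bg_big <- background[rep(seq_len(n_bg), times = C), , drop = FALSE]
  obs_of_row <- coal_obs[coal_of_row]
  for (j in seq_len(p)) {
    rows <- mask_big[coal_of_row, j]
    if (any(rows)) bg_big[[j]][rows] <- X[[j]][obs_of_row[rows]]
  }
  rownames(bg_big) <- NULL
  f <- as_matrix_pred(vf(bg_big))
  rowsum(f, coal_of_row, reorder = TRUE) / n_bg
}

#' SHAP attributions of a risk model on a dataset
#'
#' Computes per-observation, per-feature Shapley attributions of the
#' model's risk score relative to the background-average risk. The
#' `exact` method enumerates all feature subsets (p <= 10); `sampling`
#' uses antithetic permutation sampling with a per-observation seed
#' schedule. Both satisfy additivity: `base_value + rowSums(values)`
#' equals the model's risk prediction for every observation.
#'
#' @param model A `risk_model`.
#' @param X Observations to explain (e.g. the holdout test set).
#' @param background Background dataset for the expectation (use the
#'   model's training fold).
#' @param method `"sampling"` (default) or `"exact"`.
#' @param n_perm Permutations for the sampling estimator (default 64,
#'   rounded up to an even count for antithetic pairing).
#' @param seed Integer seed for the sampling estimator.
#' @return An object of class `shap_matrix`: `values` (n x p matrix),
#'   `base_value`, `pred`, `features`, `model_id`, `method`.
#' @export
shap_attributions <- function(model, X, background,
                              method = c("sampling", "exact"),
                              n_perm = 64L, seed = 1L) {
  method <- match.arg(method)
  feats <- model$features
  Xf <- model_frame(X, feats)
  bgf <- model_frame(background, feats)
  vf <- function(df) predict_risk(model, df)
  est <- shapley_estimate(vf, Xf, bgf, method, n_perm, seed)
  structure(list(values = matrix(est$values, nrow = nrow(Xf),
                                 dimnames = list(NULL, feats)),
                 base_value = unname(est$base),
                 pred = drop(est$pred),
                 features = feats, model_id = model$model_id,
                 method = method, n_perm = n_perm),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d observations x %d features (%s, model %s)\n",
              nrow(x$values), ncol(x$values), x$method, x$model_id))
  invisible(x)
}

#' Mean absolute attribution per feature
#'
#' @param shap A `shap_matrix` (or plain attribution matrix).
#' @return A data frame `feature`, `mean_abs_phi`, sorted by decreasing
#'   importance with lexicographic tie-break.
#' @export
shap_importance <- function(shap) {
  values <- if (inherits(shap, "shap_matrix")) shap$values else shap
  imp <- data.frame(feature = colnames(values),
                    mean_abs_phi = colMeans(abs(values)),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_abs_phi, imp$feature), ]
  rownames(imp) <- NULL
  imp
}

#' Aggregate SHAP matrices across repeated-CV models
#'
#' Element-wise mean of per-model attribution matrices over models fitted
#' in repeated cross-validation, producing one attribution per observation
#' and feature, plus the mean-|phi| feature ranking (ties broken
#' lexicographically by feature name).
#'
#' @param matrices List of `shap_matrix` objects sharing shape and
#'   observation order.
#' @return An object of class `aggregated_shap`: `values`, `base_value`,
#'   `l` (number of models), `ranking`.
#' @export
aggregate_shap_over_models <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  dims <- vapply(matrices, function(s) dim(s$values), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all SHAP matrices must share the same (n, p) shape",
         call. = FALSE)
  }
  values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  base_value <- mean(vapply(matrices, `[[`, numeric(1), "base_value"))
  ranking <- shap_importance(values)
  ranking$rank <- seq_len(nrow(ranking))
  structure(list(values = values, base_value = base_value,
                 l = length(matrices), ranking = ranking,
                 features = colnames(values)),
            class = "aggregated_shap")
}

#' @export
print.aggregated_shap <- function(x, ...) {
  cat(sprintf("<aggregated_shap> %d observations, %d models\n",
              nrow(x$values), x$l))
  print(head(x$ranking, 5L), row.names = FALSE)
  invisible(x)
}

#' Top-k rank frequency of features across CV models
#'
#' Counts, per feature, in how many repeated-CV models it ranked within
#' the `k` most important features by mean absolute attribution (ties
#' broken lexicographically).
#'
#' @param importance_tables List of per-model importance tables as
#'   returned by [shap_importance()].
#' @param k Rank cut (default 5).
#' @return A data frame `feature`, `count`, `frequency`.
#' @export
top_k_rank_frequency <- function(importance_tables, k = 5L) {
  stopifnot(length(importance_tables) >= 1L)
  features <- sort(unique(unlist(lapply(importance_tables,
                                        function(t) t$feature))))
  counts <- setNames(rep(0L, length(features)), features)
  for (tab in importance_tables) {
    tab <- tab[order(-tab$mean_abs_phi, tab$feature), ]
    top <- head(tab$feature, k)
    counts[top] <- counts[top] + 1L
  }
  data.frame(feature = features, count = as.integer(counts),
             frequency = as.numeric(counts) / length(importance_tables),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-group force summary of aggregated attributions
#'
#' Mean signed aggregated attribution per disease group and feature, the
#' data behind group-stratified force plots.
#'
#' @param agg An `aggregated_shap`.
#' @param groups Group label per observation (no missing values).
#' @param valid_groups Optional allowed labels; any other label errors.
#' @return A data frame `group`, `feature`, `mean_phi`.
#' @export
group_force_summary <- function(agg, groups, valid_groups = NULL) {
  stopifnot(length(groups) == nrow(agg$values))
  groups <- as.character(groups)
  bad <- is.na(groups) |
    (!is.null(valid_groups) & !(groups %in% valid_groups))
  if (any(bad)) {
    stop(sprintf("unknown group label(s): %s",
                 paste(unique(groups[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(groups)), function(gr) {
    data.frame(group = gr, feature = colnames(agg$values),
               mean_phi = colMeans(agg$values[groups == gr, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write SHAP attributions in long CSV format
#'
#' One row per (observation, feature): columns `observation`, `feature`,
#' `value`, `model_id`.
#'
#' @param shap A `shap_matrix` or `aggregated_shap`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_shap_csv <- function(shap, path) {
  values <- shap$values
  model_id <- if (inherits(shap, "shap_matrix")) shap$model_id else
    sprintf("aggregate_of_%d", shap$l)
  long <- data.frame(
    observation = rep(seq_len(nrow(values)), times = ncol(values)),
    feature = rep(colnames(values), each = nrow(values)),
    value = as.vector(values), model_id = model_id,
    stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
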