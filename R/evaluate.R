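# Concordance evaluation ------------------------------------------------------

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable iff the earlier observed time is an event
#' and the two times are not tied. A comparable pair is concordant when
#' the earlier event has the higher risk; tied risks earn half credit.
#'
#' @param time,status Survival outcome vectors (`status` 1 = event).
#' @param risk Risk scores (higher = higher mortality risk).
#' @return Concordant share of comparable pairs, in `[0, 1]`.
#' @export
harrell_c_index <- function(time, status, risk) {
  stopifnot(length(time) == length(status), length(time) == length(risk))
  if (anyNA(time) || anyNA(status) || anyNA(risk)) {
    stop("time, status and risk must not contain missing values",
         call. = FALSE)
  }
  events <- which(status == 1L)
  concordant <- 0
  comparable <- 0
  for (i in events) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0L) next
    comparable <- comparable + m
    concordant <- concordant + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (comparable == 0) {
    stop("no comparable pairs: concordance is undefined", call. = FALSE)
  }
  concordant / comparable
}

#' Evaluate an ensemble of fitted models on holdout data
#'
#' Computes the holdout C-index of every model, overall and within each
#' disease-group subset, and summarises per model family as mean and
#' standard deviation. A group without comparable pairs is reported as
#' `NA`, not an error.
#'
#' @param models List of `risk_model` objects (one or more families).
#' @param holdout Engineered holdout data with `time` and `status`.
#' @param groups Optional group label per holdout row (defaults to
#'   `holdout$disease_group` when present).
#' @return A list of class `performance_summary`: `per_model` (one row per
#'   model x subset) and `summary` (mean +/- sd per family x subset).
#' @export
evaluate_ensemble <- function(models, holdout, groups = NULL) {
  stopifnot(length(models) >= 1L)
  if (is.null(groups) && !is.null(holdout$disease_group)) {
    groups <- holdout$disease_group
  }
  subsets <- list(overall = seq_len(nrow(holdout)))
  if (!is.null(groups)) {
    for (lv in unique(as.character(groups))) {
      subsets[[lv]] <- which(as.character(groups) == lv)
    }
  }
  rows <- lapply(models, function(m) {
    risk <- predict_risk(m, holdout)
    do.call(rbind, lapply(names(subsets), function(nm) {
      idx <- subsets[[nm]]
      ci <- tryCatch(
        harrell_c_index(holdout$time[idx], holdout$status[idx], risk[idx]),
        error = function(e) NA_real_)
      data.frame(family = m$kind, model_id = m$model_id, subset = nm,
                 c_index = ci, stringsAsFactors = FALSE)
    }))
  })
  per_model <- do.call(rbind, rows)
  summary <- aggregate(c_index ~ family + subset, data = per_model,
                       FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                           sd = if (sum(!is.na(x)) > 1L)
                                             sd(x, na.rm = TRUE) else 0),
                       na.action = stats::na.pass)
  summary <- cbind(summary[c("family", "subset")],
                   mean_c_index = summary$c_index[, "mean"],
                   sd_c_index = summary$c_index[, "sd"])
  structure(list(per_model = per_model, summary = summary),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary>\n")
  print(x$summary[x$summary$subset == "overall", ], row.names = FALSE)
  invisible(x)
}

#' Write a performance summary as CSV and JSON
#'
#' @param perf A `performance_summary`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_performance_summary <- function(perf, csv_path = NULL,
                                      json_path = NULL) {
  if (!is.null(csv_path)) write.csv(perf$summary, csv_path,
                                    row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summary = perf$summary,
                              per_model = perf$per_model),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
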