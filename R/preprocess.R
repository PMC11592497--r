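# Preprocessing & feature engineering -----------------------------------------

ENGINEERED_PREDICTORS <- c(
  "sex", "weight_lt_2500g", "chrom_alterations", "disease_group",
  "heart_disease_history", "malformations", "pulm_hypertension",
  "days_admission_to_surgery", "n_previous_admissions", "crp_max",
  "leukocytes_min", "creatinine_max", "urea_max", "age_at_surgery",
  "aortic_cross_clamp_time", "circulatory_arrest", "hlm_category",
  "hypothermia_category", "open_thorax"
)

CONTINUOUS_PREDICTORS <- c(
  "days_admission_to_surgery", "n_previous_admissions", "crp_max",
  "leukocytes_min", "creatinine_max", "urea_max", "age_at_surgery",
  "aortic_cross_clamp_time"
)

#' Chained-equation imputation of missing values
#'
#' Fills missing entries by iterated conditional modelling: numeric columns
#' by predictive-mean matching (Bayesian coefficient draw, nearest-donor
#' sampling), two-level factors by a logistic draw. Observed entries are
#' never modified, and a single completed dataset is returned after
#' `n_iterations` cycles.
#'
#' @param data A data frame; list columns are ignored by the imputation
#'   models and must not contain missing entries themselves.
#' @param n_iterations Number of chained cycles (default 10).
#' @param seed Integer seed; the fill is deterministic given it.
#' @param n_donors Donor-pool size for predictive-mean matching.
#' @return The completed data frame.
#' @export
impute_chained <- function(data, n_iterations = 10L, seed = 1L,
                           n_donors = 5L) {
  assert_number(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  is_list_col <- vapply(data, is.list, logical(1))
  usable <- names(data)[!is_list_col]
  targets <- usable[vapply(usable, function(cn) anyNA(data[[cn]]), logical(1))]
  if (length(targets) == 0L) return(data)
  fully_missing <- targets[vapply(targets, function(cn) {
    all(is.na(data[[cn]]))
  }, logical(1))]
  if (length(fully_missing)) {
    stop_field(fully_missing[1], "column is fully missing; cannot impute")
  }
  # fewest-missing first, the usual visit order
  targets <- targets[order(vapply(targets, function(cn) {
    sum(is.na(data[[cn]]))
  }, numeric(1)))]
  id_like <- usable[vapply(usable, function(cn) {
    is.character(data[[cn]])
  }, logical(1))]
  predictors_of <- function(target) setdiff(usable, c(target, id_like))

  with_seed(seed, {
    miss_idx <- lapply(targets, function(cn) which(is.na(data[[cn]])))
    names(miss_idx) <- targets
    for (cn in targets) {                       # initial fill: random draws
      obs <- data[[cn]][!is.na(data[[cn]])]
      data[[cn]][miss_idx[[cn]]] <-
        sample(obs, length(miss_idx[[cn]]), replace = TRUE)
    }
    for (iter in seq_len(n_iterations)) {
      for (cn in targets) {
        mis <- miss_idx[[cn]]
        obs <- setdiff(seq_len(nrow(data)), mis)
        y_obs <- data[[cn]][obs]
        preds <- predictors_of(cn)
        df <- data[c(cn, preds)]
        if (is.numeric(data[[cn]])) {
          if (sd(y_obs) == 0) { data[[cn]][mis] <- y_obs[1]; next }
          data[[cn]][mis] <- pmm_draw(df, cn, obs, mis, n_donors)
        } else if (is.factor(data[[cn]]) && nlevels(data[[cn]]) == 2L) {
          fit <- suppressWarnings(
            glm(stats::reformulate(preds, cn), data = df[obs, , drop = FALSE],
                family = binomial()))
          p <- suppressWarnings(
            predict(fit, newdata = df[mis, , drop = FALSE],
                    type = "response"))
          lv <- levels(data[[cn]])
          data[[cn]][mis] <- factor(lv[1L + rbinom(length(mis), 1L, p)],
                                    levels = lv)
        } else {
          stop_field(cn, "only numeric and two-level factor columns can hold
                     missing values")
        }
      }
    }
  })
  data
}

# One predictive-mean-matching update for a numeric target.
pmm_draw <- function(df, target, obs, mis, n_donors) {
  fit <- suppressWarnings(
    lm(stats::reformulate(setdiff(names(df), target), target),
       data = df[obs, , drop = FALSE]))
  b <- coef(fit)
  keep <- !is.na(b)
  mm <- model.matrix(stats::delete.response(stats::terms(fit)), data = df,
                     xlev = fit$xlevels)[, keep, drop = FALSE]
  vc <- stats::vcov(fit, complete = FALSE)   # aliased terms excluded
  bstar <- b[keep] + drop(crossprod(chol(vc + diag(1e-10, nrow(vc))),
                                    rnorm(nrow(vc))))
  pred_obs <- drop(mm[obs, , drop = FALSE] %*% b[keep])
  pred_mis <- drop(mm[mis, , drop = FALSE] %*% bstar)
  y_obs <- df[[target]][obs]
  vapply(pred_mis, function(pm) {
    donors <- order(abs(pred_obs - pm))[seq_len(min(n_donors, length(obs)))]
    y_obs[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

# Engineered summary of one lab series within the 72 h window.
lab_extreme <- function(series, agg, patient, analyte) {
  s <- series[series$hour >= 0 & series$hour <= 72, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop(sprintf("patient %s has an empty %s series within 72 h",
                 patient, analyte), call. = FALSE)
  }
  if (agg == "max") max(s$value) else min(s$value)
}

#' Engineer the modelling dataset from a raw cohort
#'
#' Applies the clinical feature-engineering rules: body weight below 2500 g
#' becomes a binary marker and the continuous weight column is dropped;
#' height, age at admission and total duration of stay are dropped as
#' (near-)redundant with retained features; the hospitalisation history is
#' condensed to the most severe past disease group under the severity
#' ranking UVHD Ia > UVHD Ib > BVHD cmplx. > UVHD II/III > BVHD smpl.; and
#' each 72 h laboratory series is condensed to the clinically adverse
#' extreme (maximum for creatinine, urea and C-reactive protein, minimum
#' for leukocytes). The result carries exactly 19 predictors plus the
#' survival outcome.
#'
#' @param cohort A raw cohort with no missing values (impute first).
#' @param require_outcome Internal: if `FALSE`, `followup_days`/`status`
#'   are not required (used while simulating).
#' @return A data frame of class `engineered_dataset` with `patient_id`,
#'   the 19 predictors, and (unless `require_outcome = FALSE`) `time` and
#'   `status`.
#' @export
engineer_features <- function(cohort, require_outcome = TRUE) {
  raw_fields <- c("sex", "weight", "chrom_alterations", "disease_group",
                  "malformations", "pulm_hypertension",
                  "days_admission_to_surgery", "n_previous_admissions",
                  "age_at_surgery", "aortic_cross_clamp_time",
                  "circulatory_arrest", "hlm_category",
                  "hypothermia_category", "open_thorax")
  miss <- raw_fields[vapply(raw_fields, function(cn) anyNA(cohort[[cn]]),
                            logical(1))]
  if (length(miss)) {
    stop(sprintf("missing values in %s: impute before engineering",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  most_severe <- vapply(cohort$history_groups, function(h) {
    if (length(h) == 0L) return("none")
    HISTORY_LEVELS[max(match(h, HISTORY_LEVELS))]
  }, character(1))
  agg <- vapply(lab_params(), `[[`, character(1), "agg")
  out <- data.frame(
    patient_id = cohort$patient_id,
    sex = cohort$sex,
    weight_lt_2500g = factor(ifelse(cohort$weight < 2500, "yes", "no"),
                             levels = c("no", "yes")),
    chrom_alterations = cohort$chrom_alterations,
    disease_group = cohort$disease_group,
    heart_disease_history = factor(most_severe, levels = HISTORY_LEVELS,
                                   ordered = TRUE),
    malformations = cohort$malformations,
    pulm_hypertension = cohort$pulm_hypertension,
    days_admission_to_surgery = cohort$days_admission_to_surgery,
    n_previous_admissions = cohort$n_previous_admissions,
    stringsAsFactors = FALSE
  )
  for (an in LAB_ANALYTES) {
    col <- paste0(an, "_", agg[[an]])
    out[[col]] <- vapply(seq_len(nrow(cohort)), function(i) {
      lab_extreme(cohort[[paste0("lab_", an)]][[i]], agg[[an]],
                  cohort$patient_id[i], an)
    }, numeric(1))
  }
  out$age_at_surgery <- cohort$age_at_surgery
  out$aortic_cross_clamp_time <- cohort$aortic_cross_clamp_time
  out$circulatory_arrest <- cohort$circulatory_arrest
  out$hlm_category <- cohort$hlm_category
  out$hypothermia_category <- cohort$hypothermia_category
  out$open_thorax <- cohort$open_thorax
  if (require_outcome) {
    if (is.null(cohort$followup_days) || is.null(cohort$status)) {
      stop("cohort lacks the survival outcome (followup_days, status)",
           call. = FALSE)
    }
    out$time <- cohort$followup_days
    out$status <- as.integer(cohort$status)
  }
  out <- out[, c("patient_id", ENGINEERED_PREDICTORS,
                 if (require_outcome) c("time", "status")), drop = FALSE]
  class(out) <- c("engineered_dataset", "data.frame")
  validate_engineered(out, require_outcome)
}

validate_engineered <- function(data, require_outcome = TRUE) {
  stopifnot(all(ENGINEERED_PREDICTORS %in% names(data)))
  if (anyNA(data[ENGINEERED_PREDICTORS])) {
    stop("engineered dataset contains missing values", call. = FALSE)
  }
  if (require_outcome) {
    stopifnot(all(c("time", "status") %in% names(data)),
              all(data$time >= 0), all(data$status %in% c(0L, 1L)))
  }
  invisible(data)
}

#' Censor follow-up outliers at a global quantile
#'
#' Computes the `q` quantile of the follow-up time over the whole dataset
#' (linear interpolation between order statistics) and truncates any longer
#' follow-up to that threshold, forcing its status to censored. All other
#' rows are untouched.
#'
#' @param dataset An `engineered_dataset` (or any data frame with `time`
#'   and `status`).
#' @param q Quantile in (0, 1); default 0.995.
#' @return A list with `dataset`, `n_affected`, `n_events_affected`, and
#'   `threshold`.
#' @export
censor_followup_outliers <- function(dataset, q = 0.995) {
  assert_number(q, "q", lower = 0, upper = 1, open_lower = TRUE)
  if (q >= 1) stop_field("q", "must be below 1")
  threshold <- unname(quantile(dataset$time, q, type = 7))
  hit <- dataset$time > threshold
  res <- list(dataset = dataset,
              n_affected = sum(hit),
              n_events_affected = sum(hit & dataset$status == 1L),
              threshold = threshold)
  res$dataset$time[hit] <- threshold
  res$dataset$status[hit] <- 0L
  res
}

#' Report highly correlated continuous predictor pairs
#'
#' Screens all pairs of continuous predictors for absolute Pearson
#' correlation at or above `threshold`. The engineered 19-predictor set is
#' designed to produce an empty report on default synthetic data.
#'
#' @param dataset A data frame.
#' @param threshold Absolute-correlation cut (default 0.7).
#' @param columns Continuous columns to screen; defaults to the engineered
#'   continuous predictors present in `dataset`.
#' @return A data frame with one row per violating pair
#'   (`feature_a`, `feature_b`, `r`).
#' @export
prune_correlated <- function(dataset, threshold = 0.7, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(CONTINUOUS_PREDICTORS, names(dataset))
    if (length(columns) == 0L) {
      columns <- names(dataset)[vapply(dataset, is.numeric, logical(1))]
    }
  }
  report <- data.frame(feature_a = character(0), feature_b = character(0),
                       r = numeric(0), stringsAsFactors = FALSE)
  if (length(columns) < 2L) return(report)
  cm <- cor(as.data.frame(dataset)[columns])
  for (i in seq_len(length(columns) - 1L)) {
    for (j in seq(i + 1L, length(columns))) {
      if (is.finite(cm[i, j]) && abs(cm[i, j]) >= threshold) {
        report <- rbind(report, data.frame(
          feature_a = columns[i], feature_b = columns[j], r = cm[i, j],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(report) <- NULL
  report
}

#' Descriptive cohort summary
#'
#' Per-group and total sample sizes, event counts and mortality percentages
#' (rounded to two decimals), plus mean/sd for continuous and category
#' counts for categorical predictors.
#'
#' @param dataset An `engineered_dataset`.
#' @param group_col Grouping column (default `disease_group`).
#' @return A list of class `cohort_summary` with elements `groups`
#'   (one row per group plus a `Total` row) and `variables`.
#' @export
cohort_summary <- function(dataset, group_col = "disease_group") {
  g <- dataset[[group_col]]
  per <- lapply(levels(g), function(lv) {
    idx <- g == lv
    data.frame(group = lv, n = sum(idx),
               events = sum(dataset$status[idx] == 1L),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, per)
  groups <- rbind(groups, data.frame(group = "Total", n = nrow(dataset),
                                     events = sum(dataset$status == 1L)))
  groups$mortality_pct <- ifelse(
    groups$n > 0, round(100 * groups$events / groups$n, 2), 0)
  variables <- lapply(setNames(nm = ENGINEERED_PREDICTORS), function(cn) {
    col <- dataset[[cn]]
    if (is.numeric(col)) {
      c(mean = mean(col), sd = sd(col))
    } else {
      table(col)
    }
  })
  structure(list(groups = groups, variables = variables),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
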