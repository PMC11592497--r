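# Stratified splitting and repeated CV fold plans -----------------------------
#
# Strata cross quantile bins of the follow-up time with event status and
# disease group, so that rare events and small disease groups are spread
# evenly over the holdout split and every CV fold.

#' Strata definition for survival splitting
#'
#' @param time_bins Number of quantile bins of the follow-up time
#'   (default 5).
#' @param use_status Stratify on event status (default TRUE).
#' @param use_group Stratify on disease group (default TRUE).
#' @return An object of class `strata_definition`.
#' @export
strata_definition <- function(time_bins = 5L, use_status = TRUE,
                              use_group = TRUE) {
  assert_number(time_bins, "time_bins", lower = 1, integer = TRUE)
  assert_flag(use_status, "use_status")
  assert_flag(use_group, "use_group")
  structure(list(time_bins = time_bins, use_status = use_status,
                 use_group = use_group), class = "strata_definition")
}

# Stratum label per observation: time quantile bin x status x group.
# Duplicate quantile breaks collapse adjacent time bins, which merges
# sparse cells with their nearest time bin.
build_strata <- function(time, status, group, strata) {
  n <- length(time)
  parts <- list()
  if (strata$time_bins > 1L) {
    breaks <- unique(quantile(time, probs = seq(0, 1,
                                                length.out = strata$time_bins + 1L)))
    if (length(breaks) > 2L) {
      parts$time <- cut(time, breaks = breaks, include.lowest = TRUE,
                        labels = FALSE)
    }
  }
  if (strata$use_status) parts$status <- as.integer(status)
  if (strata$use_group && !is.null(group)) parts$group <- as.character(group)
  if (length(parts) == 0L) return(rep("all", n))
  do.call(paste, c(parts, sep = "|"))
}

#' Stratified train/holdout partition
#'
#' Splits observations into disjoint, exhaustive train and test sets so
#' that within every stratum (time bin x status x group) the train
#' fraction deviates from `ratio` by less than one observation. Singleton
#' strata go to train deterministically.
#'
#' @param time,status Survival outcome vectors.
#' @param group Optional disease-group vector.
#' @param ratio Train fraction in (0, 1); default 0.6.
#' @param strata A [strata_definition()].
#' @param seed Integer seed.
#' @return A list with integer index vectors `train_ids` and `test_ids`.
#' @export
stratified_partition <- function(time, status, group = NULL, ratio = 0.6,
                                 strata = strata_definition(), seed = 1L) {
  assert_number(ratio, "ratio", lower = 0, upper = 1, open_lower = TRUE)
  if (ratio >= 1) stop_field("ratio", "must be below 1")
  labels <- build_strata(time, status, group, strata)
  train <- logical(length(time))
  with_seed(seed, {
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      if (length(idx) == 1L) { train[idx] <- TRUE; next }
      n_train <- round(ratio * length(idx))
      pick <- sample(idx, n_train)
      train[pick] <- TRUE
    }
  })
  list(train_ids = which(train), test_ids = which(!train))
}

#' Stratified (repeated) cross-validation fold plan
#'
#' Builds `repeats` independent stratified k-fold assignments. Within each
#' repeat every observation sits in exactly one test fold; fold sizes
#' differ by at most one within each stratum; and events are allocated to
#' folds within one event of proportionality (whenever the data holds at
#' least `k` events, every fold receives at least one).
#'
#' @param time,status Survival outcome vectors.
#' @param group Optional disease-group vector.
#' @param k Number of folds (>= 2).
#' @param repeats Number of repeats (default 1).
#' @param strata A [strata_definition()].
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `k`, `repeats`,
#'   `seed`, and `assignment`, an `n x repeats` integer matrix of fold
#'   indices.
#' @export
repeated_cv_folds <- function(time, status, group = NULL, k = 10L,
                              repeats = 1L, strata = strata_definition(),
                              seed = 1L) {
  n <- length(time)
  assert_number(k, "k", lower = 2, integer = TRUE)
  assert_number(repeats, "repeats", lower = 1, integer = TRUE)
  if (k > n) stop_field("k", "cannot exceed the number of observations")
  labels <- build_strata(time, status, group, strata)
  assignment <- matrix(NA_integer_, nrow = n, ncol = repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      # One cyclic counter per status level, carried across strata: fold
      # sizes stay balanced inside each stratum (contiguous cyclic block)
      # while events remain within one of proportional over folds.
      for (st in unique(as.integer(status))) {
        counter <- sample.int(k, 1L) - 1L
        labs <- unique(labels[as.integer(status) == st])
        for (lab in sample(labs)) {
          idx <- which(labels == lab & as.integer(status) == st)
          idx <- if (length(idx) > 1L) sample(idx) else idx
          assignment[idx, r] <- (counter + seq_along(idx) - 1L) %% k + 1L
          counter <- (counter + length(idx)) %% k
        }
      }
    }
  })
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d-fold x %d repeats over %d observations\n",
              x$k, x$repeats, nrow(x$assignment)))
  invisible(x)
}

#' Serialize / read a fold plan as CSV
#'
#' Long format with one row per (observation, repeat): columns
#' `observation_id`, `repeat`, `fold`.
#'
#' @param plan A `fold_plan`.
#' @param path File path.
#' @return `write_fold_plan_csv` returns `path` invisibly;
#'   `read_fold_plan_csv` reconstructs the `fold_plan`.
#' @export
write_fold_plan_csv <- function(plan, path) {
  long <- data.frame(
    observation_id = rep(seq_len(nrow(plan$assignment)), plan$repeats),
    rep = rep(seq_len(plan$repeats), each = nrow(plan$assignment)),
    fold = as.vector(plan$assignment)
  )
  names(long)[2] <- "repeat"
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan_csv
#' @export
read_fold_plan_csv <- function(path) {
  long <- read.csv(path, check.names = FALSE)
  k <- max(long$fold)
  repeats <- max(long[["repeat"]])
  n <- max(long$observation_id)
  assignment <- matrix(NA_integer_, nrow = n, ncol = repeats)
  assignment[cbind(long$observation_id, long[["repeat"]])] <-
    as.integer(long$fold)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = NA_integer_, assignment = assignment),
            class = "fold_plan")
}
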