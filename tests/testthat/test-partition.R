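surv_toy <- function(n, seed = 1, event_rate = 0.15, n_groups = 4) {
  withr::with_seed(seed, {
    list(time = round(rlnorm(n, log(8), 0.8), 1),
         status = as.integer(runif(n) < event_rate),
         group = sample(DISEASE_GROUPS[seq_len(n_groups)], n, TRUE))
  })
}

test_that("stratified partition is disjoint, exhaustive and proportional", {
  d <- surv_toy(1302, seed = 2)
  part <- stratified_partition(d$time, d$status, d$group, ratio = 0.6,
                               seed = 5)
  expect_setequal(c(part$train_ids, part$test_ids), seq_len(1302))
  expect_length(intersect(part$train_ids, part$test_ids), 0)
  labels <- build_strata(d$time, d$status, d$group, strata_definition())
  # per-stratum train share within one observation of the ratio
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_tr <- sum(idx %in% part$train_ids)
    expect_lt(abs(n_tr - 0.6 * length(idx)), 1)
  }
  n_strata <- length(unique(labels))
  expect_lt(abs(length(part$train_ids) - round(0.6 * 1302)), n_strata + 1)
  expect_identical(stratified_partition(d$time, d$status, d$group,
                                        ratio = 0.6, seed = 5), part)
})

test_that("singleton strata are deterministically assigned to train", {
  time <- c(1, 2, 3, 4, 100)
  status <- c(0L, 0L, 0L, 0L, 1L)      # the single event is its own stratum
  part <- stratified_partition(time, status, ratio = 0.5,
                               strata = strata_definition(time_bins = 1),
                               seed = 3)
  expect_true(5 %in% part$train_ids)
})

test_that("a ratio within one observation of 1 keeps everything in train", {
  d <- surv_toy(60, seed = 4, n_groups = 2)
  part <- stratified_partition(d$time, d$status, d$group, ratio = 0.999,
                               seed = 1)
  expect_length(part$test_ids, 0)
})

test_that("fold plans are exhaustive with balanced strata and events", {
  d <- surv_toy(520, seed = 7)
  plan <- repeated_cv_folds(d$time, d$status, d$group, k = 10, repeats = 10,
                            seed = 9)
  expect_equal(dim(plan$assignment), c(520L, 10L))
  expect_equal(plan$repeats * plan$k, 100L)  # 100 training tasks
  labels <- build_strata(d$time, d$status, d$group, strata_definition())
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignment[, r]
    expect_setequal(unique(fold), 1:10)
    expect_equal(tabulate(fold, 10), as.vector(table(factor(fold, 1:10))))
    # fold sizes within each stratum differ by at most one
    for (lab in unique(labels)) {
      cnt <- tabulate(fold[labels == lab], 10)
      expect_lte(max(cnt) - min(cnt), 1L)
    }
    # events within one of proportional allocation
    ev <- tabulate(fold[d$status == 1L], 10)
    expect_lte(max(ev) - min(ev), 1L)
  }
})

test_that("every fold receives an event whenever events >= k", {
  for (s in 1:20) {
    d <- surv_toy(60, seed = s, event_rate = 0.12, n_groups = 3)
    if (sum(d$status) < 5) next
    plan <- repeated_cv_folds(d$time, d$status, d$group, k = 5, repeats = 2,
                              seed = s)
    for (r in 1:2) {
      ev <- tabulate(plan$assignment[d$status == 1L, r], 5)
      expect_true(all(ev >= 1))
    }
  }
})

test_that("leave-one-out and error cases behave", {
  d <- surv_toy(12, seed = 3, n_groups = 1)
  plan <- repeated_cv_folds(d$time, d$status, group = NULL, k = 12,
                            repeats = 1,
                            strata = strata_definition(time_bins = 1,
                                                       use_group = FALSE))
  expect_setequal(plan$assignment[, 1], 1:12)
  expect_error(repeated_cv_folds(d$time, d$status, k = 13), "k")
  expect_error(repeated_cv_folds(d$time, d$status, k = 1), "k")
})

test_that("fold plans survive the CSV round trip", {
  d <- surv_toy(40, seed = 6)
  plan <- repeated_cv_folds(d$time, d$status, d$group, k = 4, repeats = 3,
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fold_plan_csv(plan, path)
  back <- read_fold_plan_csv(path)
  expect_equal(back$assignment, plan$assignment)
  expect_equal(back$k, plan$k)
  expect_equal(back$repeats, plan$repeats)
})
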