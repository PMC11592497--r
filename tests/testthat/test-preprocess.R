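test_that("chained imputation fills gaps without touching observed data", {
  df <- withr::with_seed(31, data.frame(
    a = rnorm(400, 5, 1), b = rnorm(400), c = runif(400),
    f = factor(sample(c("no", "yes"), 400, TRUE), levels = c("no", "yes"))
  ))
  expect_identical(impute_chained(df), df)

  holed <- df
  holed$a[sample(400, 40)] <- NA
  done <- impute_chained(holed, seed = 1)
  expect_false(anyNA(done$a))
  obs <- !is.na(holed$a)
  expect_identical(done$a[obs], df$a[obs])
  expect_identical(impute_chained(holed, seed = 1), done)
  expect_false(identical(impute_chained(holed, seed = 2), done))

  const <- df
  const$a <- 7
  const$a[1:40] <- NA
  expect_true(all(impute_chained(const, seed = 1)$a == 7))

  gone <- df
  gone$a <- NA_real_
  expect_error(impute_chained(gone), "fully missing")
})

test_that("PMM recovers the centre of an MCAR-perforated normal column", {
  for (s in 1:3) {
    df <- withr::with_seed(100 + s, {
      x <- rnorm(2000)
      data.frame(y = 5 + 0.5 * x + rnorm(2000, 0, sqrt(0.75)), x = x)
    })
    holed <- df
    holed$y[withr::with_seed(200 + s, sample(2000, 200))] <- NA
    done <- impute_chained(holed, seed = s)
    expect_lt(abs(mean(done$y) - 5), 0.2)
  }
})

test_that("binary factor imputation draws from a logistic fit", {
  df <- withr::with_seed(41, {
    x <- rnorm(1000)
    p <- stats::plogis(2 * x)
    data.frame(x = x, f = factor(ifelse(runif(1000) < p, "yes", "no"),
                                 levels = c("no", "yes")))
  })
  holed <- df
  holed$f[1:150] <- NA
  done <- impute_chained(holed, seed = 1)
  expect_false(anyNA(done$f))
  # imputed values should track the covariate direction
  imp <- done$f[1:150]
  expect_gt(mean(df$x[1:150][imp == "yes"]), mean(df$x[1:150][imp == "no"]))
})

test_that("feature engineering applies the clinical recoding rules", {
  co <- generate_cohort(cohort_spec(seed = 17))
  co$weight[1] <- 2499
  co$weight[2] <- 2500
  co$history_groups[[3]] <- c("BVHD smpl.", "UVHD Ia")
  co$history_groups[[4]] <- c("BVHD cmplx.", "UVHD II/III")
  co$lab_creatinine[[5]] <- data.frame(hour = c(4, 30, 70),
                                       value = c(0.30, 0.50, 0.44))
  co$lab_urea[[6]] <- data.frame(hour = 10, value = 41)
  eng <- engineer_features(co)
  expect_identical(sort(setdiff(names(eng),
                                c("patient_id", "time", "status"))),
                   sort(ENGINEERED_PREDICTORS))
  expect_false(any(c("weight", "height", "age_at_admission") %in%
                     names(eng)))
  expect_equal(as.character(eng$weight_lt_2500g[1:2]), c("yes", "no"))
  expect_equal(as.character(eng$heart_disease_history[3]), "UVHD Ia")
  expect_equal(as.character(eng$heart_disease_history[4]), "BVHD cmplx.")
  expect_equal(eng$creatinine_max[5], 0.50)
  expect_equal(eng$urea_max[6], 41)

  co$lab_crp[[7]] <- data.frame(hour = numeric(0), value = numeric(0))
  expect_error(engineer_features(co), "P0007.*crp|crp.*P0007")
})

test_that("engineering requires imputation first and re-validates", {
  co <- generate_cohort(cohort_spec(seed = 18))
  co$weight[5] <- NA
  expect_error(engineer_features(co), "impute")
  eng <- engineer_features(impute_chained(co, seed = 1))
  expect_silent(validate_engineered(eng))
})

test_that("follow-up outlier censoring matches a brute-force scan", {
  ds <- data.frame(time = as.numeric(1:200),
                   status = rep(c(1L, 0L), 100))
  res <- censor_followup_outliers(ds, q = 0.995)
  thr <- quantile(ds$time, 0.995, type = 7)
  expect_equal(res$threshold, unname(thr))
  expect_equal(res$n_affected, sum(ds$time > thr))
  expect_equal(res$n_events_affected, sum(ds$time > thr & ds$status == 1L))
  expect_true(all(res$dataset$time <= thr))
  expect_true(all(res$dataset$time <= ds$time))
  # no censored observation may become an event
  expect_true(all(!(ds$status == 0L & res$dataset$status == 1L)))
  # a late death is truncated and censored
  ds2 <- data.frame(time = c(rep(5, 400), 260), status = c(rep(0L, 400), 1L))
  res2 <- censor_followup_outliers(ds2, q = 0.995)
  expect_lt(res2$threshold, 260)
  expect_equal(res2$dataset$time[401], res2$threshold)
  expect_equal(res2$dataset$status[401], 0L)
  # untouched when nothing exceeds the threshold
  ds3 <- data.frame(time = rep(3, 10), status = rep(0L, 10))
  expect_equal(censor_followup_outliers(ds3, 0.995)$n_affected, 0)
})

test_that("correlation pruning reports exactly the violating pairs", {
  x <- withr::with_seed(51, rnorm(5000))
  df <- data.frame(a = x, b = x, c = withr::with_seed(52, rnorm(5000)))
  rep1 <- prune_correlated(df, columns = c("a", "b", "c"))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$r, 1.0)
  expect_setequal(c(rep1$feature_a, rep1$feature_b), c("a", "b"))
  rep2 <- prune_correlated(df[c("a", "c")], columns = c("a", "c"))
  expect_equal(nrow(rep2), 0L)
  # the shipped predictor set stays below the cut on default synthetic data
  eng <- engineer_features(generate_cohort(cohort_spec(seed = 19)))
  expect_equal(nrow(prune_correlated(eng)), 0L)
})

test_that("cohort summary reproduces group and total mortality", {
  ds <- data.frame(
    disease_group = factor(rep(DISEASE_GROUPS, times = c(50, 111, 291, 850)),
                           levels = DISEASE_GROUPS),
    time = 1,
    status = unlist(mapply(function(n, e) c(rep(1L, e), rep(0L, n - e)),
                           c(50, 111, 291, 850), c(31, 8, 28, 6))))
  for (p in setdiff(ENGINEERED_PREDICTORS, "disease_group")) ds[[p]] <- 1
  s <- cohort_summary(ds)
  expect_equal(s$groups$mortality_pct,
               c(62.00, 7.21, 9.62, 0.71, 5.61))
  expect_equal(s$groups$n[5], sum(s$groups$n[1:4]))
  expect_equal(s$groups$events[5], sum(s$groups$events[1:4]))
  ds$status <- 0L
  expect_true(all(cohort_summary(ds)$groups$mortality_pct == 0))
})
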