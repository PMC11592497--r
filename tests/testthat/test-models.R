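test_that("configurations are validated against the search-space bounds", {
  expect_silent(rsf_config(num_trees = 100, max_depth = 40, mtry = 2,
                           min_node_size = 20, sample_fraction = 0.63))
  expect_error(rsf_config(mtry = 1), "mtry")
  expect_error(rsf_config(num_trees = 50), "num_trees")
  expect_error(boosted_cox_config(learning_rate = 0), "learning_rate")
  expect_error(boosted_cox_config(learning_rate = 0.5), "learning_rate")
  expect_error(boosted_cox_config(max_depth = 0), "max_depth")
  expect_silent(boosted_cox_config(learning_rate = 0.11, max_depth = 5,
                                   subsample = 0.5, colsample_bytree = 0.8,
                                   min_child_weight = 1))
})

test_that("RSF separates a determining covariate and stays at chance on noise", {
  # carriers die early; non-carriers are discharged (censored) at day 50,
  # so nearly all comparable pairs are carrier-vs-non-carrier
  df <- withr::with_seed(61, {
    bad <- rbinom(400, 1, 0.2)
    data.frame(
      bad = factor(ifelse(bad == 1, "yes", "no"), levels = c("no", "yes")),
      noise = rnorm(400),
      time = ifelse(bad == 1, rexp(400, 1), 50),
      status = as.integer(bad == 1))
  })
  tr <- df[1:260, ]
  te <- df[261:400, ]
  m <- fit_rsf(tr, rsf_config(num_trees = 200, min_node_size = 5), seed = 1,
               features = c("bad", "noise"))
  expect_gt(harrell_c_index(te$time, te$status, predict_risk(m, te)), 0.9)

  noise <- withr::with_seed(62, data.frame(
    x1 = rnorm(600), x2 = rnorm(600),
    time = rexp(600, 0.2), status = as.integer(runif(600) < 0.5)))
  mn <- fit_rsf(noise[1:400, ], rsf_config(num_trees = 200), seed = 1,
                features = c("x1", "x2"))
  ci <- harrell_c_index(noise$time[401:600], noise$status[401:600],
                        predict_risk(mn, noise[401:600, ]))
  expect_lt(abs(ci - 0.5), 0.06)
  expect_error(fit_rsf(transform(noise[1:10, ], status = 0L),
                       features = c("x1", "x2")), "events")
})

test_that("RSF survival functions are proper and risks match the CHF sum", {
  df <- mini_engineered(400, seed = 63)
  m <- fit_rsf(df[1:300, ], seed = 2,
               features = c("creatinine_max", "urea_max", "age_at_surgery"))
  times <- c(0, 1, 5, 10, 30, 1000)
  S <- predict_survival(m, df[301:340, ], times)
  expect_equal(dim(S), c(40L, 6L))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(S[, 1] == 1))                    # S(0) = 1
  expect_true(all(diff(t(S)) <= 1e-12))            # non-increasing
  risk <- predict_risk(m, df[301:340, ])
  expect_true(all(is.finite(risk)))
  # risk ordering is invariant to row order
  perm <- withr::with_seed(3, sample(40))
  expect_equal(predict_risk(m, df[301:340, ][perm, ]), risk[perm])
})

test_that("boosted Cox recovers a planted linear predictor", {
  d <- sim_cox_data(2000, beta = c(0.8, -0.5, 0), seed = 64)
  tr <- d[1:1400, ]
  va <- d[1401:2000, ]
  m <- fit_boosted_cox(tr, boosted_cox_config(max_depth = 2,
                                              learning_rate = 0.1,
                                              num_rounds = 2000,
                                              early_stopping_rounds = 50),
                       validation = va, seed = 1,
                       features = c("x1", "x2", "x3"))
  lp_true <- 0.8 * va$x1 - 0.5 * va$x2
  rho <- cor(predict_risk(m, va), lp_true, method = "spearman")
  expect_gt(rho, 0.7)
  expect_gt(m$meta$num_rounds_used, 0)
  expect_lte(m$meta$num_rounds_used, 2000)
})

test_that("boosted Cox edge cases: early stopping needs validation, zero rounds give constant risk", {
  d <- sim_cox_data(200, beta = c(0.8), seed = 65)
  expect_error(fit_boosted_cox(d, features = "x1"), "validation")
  m0 <- fit_boosted_cox(d, boosted_cox_config(num_rounds = 0,
                                              early_stopping_rounds = NULL),
                        features = "x1")
  expect_equal(predict_risk(m0, d), rep(0, 200))
  expect_error(predict_survival(m0, d, 1:3), "survival")
})

test_that("CPH recovers planted coefficients and flags degenerate designs", {
  d <- sim_cox_data(5000, beta = c(0.8, 0), seed = 66, censor_rate = 0.3)
  m <- fit_cph(d, features = c("x1", "x2"))
  sm <- summary(m$fit)$coefficients
  expect_lt(abs(sm["x1", "coef"] - 0.8), 2 * sm["x1", "se(coef)"])
  expect_lt(abs(sm["x2", "coef"]), 2 * sm["x2", "se(coef)"])
  # survival-function capability via the Breslow baseline
  times <- c(0, quantile(d$time, c(0.25, 0.5, 0.75)))
  S <- predict_survival(m, d[1:5, ], times)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(abs(S[, 1] - 1) < 1e-9))
  expect_true(all(diff(t(S)) <= 1e-12))

  d2 <- d[1:300, ]
  d2$x3 <- d2$x1
  expect_error(fit_cph(d2, features = c("x1", "x2", "x3")), "collinear")
  d3 <- sim_cox_data(40, beta = c(0.5, 0, 0), seed = 67)
  d3$status <- c(1L, 1L, rep(0L, 38))
  expect_warning(fit_cph(d3, features = c("x1", "x2", "x3")), "events")
})
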