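test_that("exact attributions of an additive (linear CPH) model are closed form", {
  d <- sim_cox_data(400, beta = c(1, -0.7, 0.4), seed = 81)
  m <- fit_cph(d, features = c("x1", "x2", "x3"))
  b <- coef(m$fit)
  X <- d[1:12, ]
  bg <- d[101:180, ]
  sm <- shap_attributions(m, X, bg, method = "exact")
  for (j in 1:3) {
    expected <- b[j] * (X[[paste0("x", j)]] - mean(bg[[paste0("x", j)]]))
    expect_equal(unname(sm$values[, j]), unname(expected),
                 tolerance = 1e-9)
  }
  # additivity: base + sum phi = prediction
  expect_equal(sm$base_value + rowSums(sm$values), sm$pred,
               tolerance = 1e-9)
})

test_that("sampling attributions agree with exact enumeration at p = 6", {
  d <- sim_cox_data(400, beta = c(0.9, -0.6, 0.4, 0.3, 0, 0), seed = 82)
  m <- fit_boosted_cox(d[1:300, ],
                       boosted_cox_config(max_depth = 2,
                                          learning_rate = 0.1,
                                          num_rounds = 150,
                                          early_stopping_rounds = NULL),
                       seed = 1, features = paste0("x", 1:6))
  X <- d[301:305, ]
  bg <- d[1:20, ]
  ex <- shap_attributions(m, X, bg, method = "exact")
  sa <- shap_attributions(m, X, bg, method = "sampling", n_perm = 800,
                          seed = 4)
  expect_lt(max(abs(ex$values - sa$values)), 0.1)
  # both estimators are exactly additive per observation
  expect_equal(ex$base_value + rowSums(ex$values), ex$pred,
               tolerance = 1e-9)
  expect_equal(sa$base_value + rowSums(sa$values), sa$pred,
               tolerance = 1e-9)
})

test_that("a feature the model cannot use receives zero attribution", {
  d <- sim_cox_data(300, beta = c(0.9), seed = 83)
  d$flat <- withr::with_seed(86, rnorm(300))  # varies, but unused below
  m <- fit_cph(d[1:200, ], features = "x1")
  m$features <- c("x1", "flat")       # expose the inert feature
  sm <- shap_attributions(m, d[201:210, ], d[1:50, ], method = "exact")
  expect_lt(max(abs(sm$values[, "flat"])), 1e-12)
  expect_gt(max(abs(sm$values[, "x1"])), 0.1)
})

test_that("exact enumeration refuses more than 10 features", {
  d <- sim_cox_data(60, beta = rep(0.1, 11), seed = 84)
  m <- fit_cph(d, features = paste0("x", 1:11))
  expect_error(shap_attributions(m, d[1:2, ], d[1:20, ], method = "exact"),
               "sampling")
})

test_that("cross-model aggregation is the element-wise mean", {
  mk <- function(seed) {
    v <- withr::with_seed(seed, matrix(rnorm(40), 8, 5,
                                       dimnames = list(NULL,
                                                       paste0("f", 1:5))))
    structure(list(values = v, base_value = seed / 10,
                   pred = rowSums(v) + seed / 10,
                   features = paste0("f", 1:5),
                   model_id = paste0("m", seed), method = "exact"),
              class = "shap_matrix")
  }
  one <- aggregate_shap_over_models(list(mk(1)))
  expect_equal(one$values, mk(1)$values, tolerance = 1e-15)
  mats <- list(mk(1), mk(2), mk(3))
  agg <- aggregate_shap_over_models(mats)
  direct <- (mk(1)$values + mk(2)$values + mk(3)$values) / 3
  expect_equal(agg$values, direct, tolerance = 1e-12)
  expect_equal(agg$base_value, mean(c(0.1, 0.2, 0.3)), tolerance = 1e-12)
  # linearity consistency: mean over models of (base_k + sum phi_k)
  # equals aggregate base + sum aggregate phi
  lhs <- Reduce(`+`, lapply(mats, function(s) s$base_value +
                              rowSums(s$values))) / 3
  expect_equal(agg$base_value + rowSums(agg$values), lhs,
               tolerance = 1e-12)
  bad <- mk(4)
  bad$values <- bad$values[, 1:4]
  expect_error(aggregate_shap_over_models(list(mk(1), bad)), "shape")
})

test_that("importance ranking breaks ties lexicographically", {
  v <- matrix(c(1, -1, 1, -1, 0.5, 0.5), nrow = 2,
              dimnames = list(NULL, c("b_feat", "a_feat", "c_feat")))
  imp <- shap_importance(v)
  expect_equal(imp$feature, c("a_feat", "b_feat", "c_feat"))
  expect_equal(imp$mean_abs_phi, c(1, 1, 0.5))
})

test_that("top-k rank frequency matches hand enumeration", {
  t1 <- data.frame(feature = c("a", "b", "c"), mean_abs_phi = c(3, 2, 1))
  t2 <- data.frame(feature = c("a", "b", "c"), mean_abs_phi = c(1, 3, 2))
  t3 <- data.frame(feature = c("a", "b", "c"), mean_abs_phi = c(2, 1, 3))
  rf <- top_k_rank_frequency(list(t1, t2, t3), k = 2)
  expect_equal(rf$count[rf$feature == "a"], 2L)
  expect_equal(rf$count[rf$feature == "b"], 2L)
  expect_equal(rf$count[rf$feature == "c"], 2L)
  rf1 <- top_k_rank_frequency(list(t1), k = 1)
  expect_equal(rf1$count, c(1L, 0L, 0L))
})

test_that("group force summaries are exact group-by means", {
  v <- withr::with_seed(85, matrix(rnorm(60), 12, 5,
                                   dimnames = list(NULL, paste0("f", 1:5))))
  agg <- structure(list(values = v, base_value = 0, l = 1,
                        features = colnames(v)),
                   class = "aggregated_shap")
  groups <- rep(c("g1", "g2"), each = 6)
  fs <- group_force_summary(agg, groups)
  for (gr in c("g1", "g2")) {
    expect_equal(fs$mean_phi[fs$group == gr],
                 unname(colMeans(v[groups == gr, ])), tolerance = 1e-12)
  }
  # mirrored attributions give opposite-sign summaries
  v2 <- rbind(v[1:6, ], -v[1:6, ])
  agg2 <- structure(list(values = v2, base_value = 0, l = 1,
                         features = colnames(v)),
                    class = "aggregated_shap")
  fs2 <- group_force_summary(agg2, groups)
  expect_equal(fs2$mean_phi[fs2$group == "g1"],
               -fs2$mean_phi[fs2$group == "g2"], tolerance = 1e-12)
  expect_error(group_force_summary(agg, groups,
                                   valid_groups = c("g1")), "unknown")
})
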