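test_that("time grids are unique event times, thinned beyond the cap", {
  time <- c(1, 2, 2, 3, 10, 11, 12)
  status <- c(1L, 1L, 0L, 1L, 1L, 0L, 1L)
  expect_equal(time_grid(time, status), c(1, 2, 3, 10, 12))
  long <- time_grid(seq_len(500), rep(1L, 500), max_points = 50)
  expect_lte(length(long), 50)
  expect_true(all(long %in% seq_len(500)))
  expect_error(time_grid(1:3, rep(0L, 3)), "event")
})

test_that("SurvSHAP(t) on a two-feature CPH is additive with coefficient-consistent signs", {
  d <- sim_cox_data(500, beta = c(1, -1), seed = 91, censor_rate = 0.3)
  m <- fit_cph(d, features = c("x1", "x2"))
  bg <- d[1:60, ]
  grid <- unname(quantile(d$time, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  # explain an observation above the background mean in both features
  X <- d[which(d$x1 > mean(bg$x1) + 0.5 & d$x2 > mean(bg$x2) + 0.5), ][1:3, ]
  cur <- survshap_curves(m, X, bg, grid = grid, method = "exact")
  # per-time additivity: sum_j phi_t = S(t|x) - Sbar(t)
  for (ti in seq_along(grid)) {
    lhs <- rowSums(cur$values[, , ti])
    rhs <- cur$pred_curves[, ti] - cur$base_curve[ti]
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  # positive coefficient + above-background value -> survival pushed down;
  # negative coefficient + above-background value -> survival pushed up
  expect_true(all(rowSums(cur$values[, "x1", ]) < 0))
  expect_true(all(rowSums(cur$values[, "x2", ]) > 0))
  mid <- which(cur$base_curve > 0.2 & cur$base_curve < 0.8)
  expect_true(all(cur$values[, "x1", mid] < 0))
  expect_true(all(cur$values[, "x2", mid] > 0))
})

test_that("sampling SurvSHAP(t) is additive per time point too", {
  df <- mini_engineered(300, seed = 92)
  feats <- c("creatinine_max", "urea_max", "open_thorax", "age_at_surgery")
  m <- fit_rsf(df[1:200, ], rsf_config(num_trees = 100), seed = 1,
               features = feats)
  grid <- time_grid(df$time[1:200], df$status[1:200], max_points = 12)
  cur <- survshap_curves(m, df[201:206, ], df[1:25, ], grid = grid,
                         n_perm = 10, seed = 3)
  for (ti in seq_along(grid)) {
    expect_equal(rowSums(cur$values[, , ti]),
                 cur$pred_curves[, ti] - cur$base_curve[ti],
                 tolerance = 1e-9)
  }
  # constant survival beyond the last event time gives constant curves
  grid2 <- c(max(grid), max(df$time) + c(10, 100))
  cur2 <- survshap_curves(m, df[201:203, ], df[1:25, ], grid = grid2,
                          n_perm = 6, seed = 3)
  expect_equal(cur2$values[, , 2], cur2$values[, , 3], tolerance = 1e-12)
})

test_that("models without survival functions are rejected, inert models give zero curves", {
  d <- sim_cox_data(150, beta = c(0.5, 0.2), seed = 93)
  mb <- fit_boosted_cox(d, boosted_cox_config(num_rounds = 10,
                                              early_stopping_rounds = NULL),
                        seed = 1, features = c("x1", "x2"))
  expect_error(survshap_curves(mb, d[1:2, ], d[1:20, ], grid = c(1, 2)),
               "survival function")
  # constant covariates: the forest cannot split, all curves vanish
  dc <- d
  dc$x1 <- 1
  dc$x2 <- 2
  mc <- fit_rsf(dc[1:100, ], rsf_config(num_trees = 100), seed = 1,
                features = c("x1", "x2"))
  cur <- survshap_curves(mc, dc[101:104, ], dc[1:30, ],
                         grid = c(0.5, 1, 2), n_perm = 4, seed = 2)
  expect_true(all(cur$values == 0))
})

test_that("global and aggregated-global curves are exact means", {
  mkcur <- function(seed) {
    v <- withr::with_seed(seed, array(rnorm(4 * 3 * 6), dim = c(4, 3, 6),
                                      dimnames = list(NULL,
                                                      c("a", "b", "c"),
                                                      NULL)))
    structure(list(values = v, grid = 1:6, base_curve = rep(0.5, 6),
                   pred_curves = matrix(0, 4, 6), features = c("a", "b",
                                                               "c"),
                   model_id = paste0("m", seed), method = "exact"),
              class = "survshap_curves")
  }
  c1 <- mkcur(1)
  g1 <- global_survshap(c1)
  expect_equal(g1$values, apply(c1$values, c(2, 3), mean),
               tolerance = 1e-12)
  single <- c1
  single$values <- c1$values[1, , , drop = FALSE]
  expect_equal(global_survshap(single)$values,
               c1$values[1, , ], tolerance = 1e-15)
  zero <- c1
  zero$values[] <- 0
  expect_true(all(global_survshap(zero)$values == 0))

  gl <- lapply(1:5, function(s) global_survshap(mkcur(s)))
  agg <- aggregate_survshap_over_models(gl)
  direct <- Reduce(`+`, lapply(gl, `[[`, "values")) / 5
  expect_equal(agg$values, direct, tolerance = 1e-12)
  expect_equal(aggregate_survshap_over_models(gl[1])$values, gl[[1]]$values,
               tolerance = 1e-15)
  bad <- gl[[2]]
  bad$grid <- bad$grid + 1
  expect_error(aggregate_survshap_over_models(list(gl[[1]], bad)), "grid")
})
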