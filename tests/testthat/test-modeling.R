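# A small planted study used across the modeling tests (binary features
# train quickly and cleanly).
small_study <- function() {
  memo_fixture("modeling_small", generate_planted_dataset(
    planted_signal_spec(300, 40, 8, rep(0.5, 8), noise_sd = 0.2,
                        feature_kind = "binary", baseline = 6, seed = 21)))
}

test_that("evaluate reproduces hand-computed statistics", {
  ev <- evaluate(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ev$r_squared, 1.0)
  expect_equal(ev$rmse, 0.0)
  ev2 <- evaluate(c(5, 6, 7), c(6, 7, 8))
  expect_equal(ev2$r_squared, 1.0)
  expect_equal(ev2$rmse, 1.0)
  y <- c(1, 2, 3, 4); p <- c(1.1, 1.9, 3.2, 3.8)
  ev3 <- evaluate(y, p)
  expect_equal(ev3$r_squared, cor(y, p)^2, tolerance = 1e-12)
  expect_equal(ev3$r_squared, 0.981777777778, tolerance = 1e-9)
  expect_equal(ev3$rmse, sqrt(mean((y - p)^2)), tolerance = 1e-12)
  expect_equal(ev3$rmse, 0.1581, tolerance = 1e-4)
  expect_error(evaluate(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(evaluate(c(1, 2), c(1, 2)), "at least 3")
  # PRESS form differs from Pearson-squared under miscalibration
  expect_lt(evaluate(y, p + 2, method = "press")$r_squared,
            evaluate(y, p + 2, method = "pearson")$r_squared)
})

test_that("training is deterministic and importances are normalized", {
  d <- small_study()
  X <- d$fingerprints$values; y <- d$activity
  cfg <- rf_config(100, "sqrt", 1, seed = 5)
  f1 <- train_rf(X, y, cfg)
  f2 <- train_rf(X, y, cfg)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_equal(sum(f1$gini_importances), 1, tolerance = 1e-9)
  expect_true(all(f1$gini_importances >= 0))
  Xna <- X; Xna[1, 1] <- NA
  expect_error(train_rf(Xna, y, cfg), "missing values")
  # strong noiseless signal is interpolated on the training rows
  d0 <- generate_planted_dataset(
    planted_signal_spec(200, 20, 5, rep(1, 5), noise_sd = 0,
                        feature_kind = "binary", seed = 31))
  f0 <- train_rf(d0$fingerprints$values, d0$activity, cfg)
  expect_gt(evaluate(d0$activity,
                     predict(f0, d0$fingerprints$values))$r_squared, 0.95)
})

test_that("cross-validation holds out every row exactly once", {
  d <- small_study()
  X <- d$fingerprints$values; y <- d$activity
  cv <- cross_validate(X, y, rf_config(50, "third", 5, seed = 2),
                       folds = 10, seed = 6)
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_equal(tabulate(cv$fold_id), rep(30, 10))
  expect_gt(cv$q2_cv, 0.5)   # strong planted signal is learnable
  # pure noise carries no signal
  set.seed(8)
  ynoise <- rnorm(nrow(X))
  cvn <- cross_validate(X, ynoise, rf_config(50, "third", 5, seed = 2),
                        folds = 10, seed = 6)
  expect_lt(cvn$q2_cv, 0.2)
  expect_error(cross_validate(X[1:15, ], y[1:15], folds = 10), "fewer than 2")
})

test_that("tuning returns the argmax with deterministic tie-breaks", {
  d <- small_study()
  X <- d$fingerprints$values[1:150, ]; y <- d$activity[1:150]
  one <- tune_rf(X, y, grid = list(n_trees = 50L, max_features = "sqrt",
                                   min_samples_leaf = 5L),
                 folds = 5, seed = 3)
  expect_equal(one$n_trees, 50L)
  expect_identical(one$max_features, "sqrt")
  # duplicated candidates cannot produce an ambiguous winner
  dup <- tune_rf(X, y, grid = list(n_trees = c(50L, 50L),
                                   max_features = "sqrt",
                                   min_samples_leaf = 5L),
                 folds = 5, seed = 3)
  expect_equal(dup$n_trees, 50L)
  # a sensible mtry beats the degenerate single-feature candidate
  both <- tune_rf(X, y, grid = list(n_trees = 50L,
                                    max_features = list("third", 1L),
                                    min_samples_leaf = 5L),
                  folds = 5, seed = 3)
  scores <- attr(both, "grid_scores")
  expect_gt(scores$q2_cv[scores$max_features == "third"],
            scores$q2_cv[scores$max_features == "1"])
  expect_identical(both$max_features, "third")
})

test_that("feature ranking orders by importance with stable ties", {
  d <- small_study()
  fit <- train_rf(d$fingerprints$values, d$activity,
                  rf_config(200, "third", 2, seed = 4))
  full <- rank_features(fit, k = ncol(d$fingerprints$values))
  expect_setequal(full$feature, colnames(d$fingerprints$values))
  expect_true(all(diff(full$importance) <= 0))
  expect_warning(rank_features(fit, k = 999), "exceeds")
  # planted informative features dominate the ranking
  top <- rank_features(fit, 20)
  expect_gte(sum(d$truth$informative %in% top$feature), 8)
  # equal importances fall back to name order
  fake <- fit
  fake$gini_importances[] <- 1 / length(fake$gini_importances)
  rk <- rank_features(fake, 5)
  expect_identical(rk$feature, sort(names(fake$gini_importances))[1:5])
})

test_that("top-k refit degrades gracefully and k = p reproduces the model", {
  d <- small_study()
  X <- d$fingerprints$values; y <- d$activity
  cfg <- rf_config(100, "third", 2, seed = 9)
  fit <- train_rf(X, y, cfg)
  cv <- cross_validate(X, y, cfg, folds = 5, seed = 11)
  full_rep <- performance_report(y, predict(fit, X), cv)

  all_k <- refit_top_k(X, y, fit, k = ncol(X), folds = 5, cv_seed = 11)
  expect_equal(all_k$report$r2_train, full_rep$r2_train, tolerance = 1e-12)
  expect_equal(all_k$report$q2_cv, full_rep$q2_cv, tolerance = 1e-12)

  top20 <- refit_top_k(X, y, fit, k = 20, folds = 5, cv_seed = 11)
  expect_lt(abs(top20$report$q2_cv - full_rep$q2_cv), 0.1)

  one <- refit_top_k(X, y, fit, k = 1, folds = 5, cv_seed = 11)
  expect_lt(one$report$q2_cv, full_rep$q2_cv)
})

test_that("CV cannot beat resubstitution beyond noise on planted data", {
  d <- small_study()
  X <- d$fingerprints$values; y <- d$activity
  for (seed in c(2, 7)) {
    cfg <- rf_config(100, "sqrt", 5, seed = seed)
    fit <- train_rf(X, y, cfg)
    r2 <- evaluate(y, predict(fit, X))$r_squared
    cv <- cross_validate(X, y, cfg, folds = 5, seed = seed)
    expect_lte(cv$q2_cv, r2 + 0.05)
  }
})
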