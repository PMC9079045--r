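test_that("an uncorrupted table is all-exact and fully survives", {
  g <- generate_activity_table(table_corruption_spec(10, seed = 1))
  expect_equal(nrow(g$table), 10)
  expect_true(all(g$table$standard_relation == "="))
  expect_true(all(g$ledger$rows$rule == "none"))
  expect_equal(nrow(g$ledger$expected_compounds), 10)
})

test_that("censoring fractions are realized exactly", {
  g <- generate_activity_table(
    table_corruption_spec(10, frac_censored_gt = 0.2, seed = 2))
  expect_equal(sum(g$table$standard_relation == ">"), 2)
  expect_equal(sum(g$ledger$rows$rule == "divert_gt"), 2)
  expect_equal(nrow(g$ledger$expected_gt), 2)
})

test_that("duplicate groups are emitted as replicates and curate to the ledger", {
  g <- generate_activity_table(
    table_corruption_spec(20, dup_rate = 0.25, dup_replicates = 3,
                          dup_noise_sd = 0.05, seed = 3))
  reps <- table(g$table$molecule_id)
  expect_equal(sum(reps == 3), 5)
  expect_equal(nrow(g$table), 20 - 5 + 5 * 3)
  cur <- curate(g$table)
  expect_setequal(cur$compounds$canonical_smiles,
                  g$ledger$expected_compounds$canonical_smiles)
  m <- merge(cur$compounds, g$ledger$expected_compounds,
             by = "canonical_smiles")
  expect_equal(m$pic50.x, m$pic50.y, tolerance = 1e-9)
})

test_that("generation is seed-deterministic with stable ledger structure", {
  spec <- table_corruption_spec(25, frac_censored_gt = 0.2, frac_salts = 0.2,
                                dup_rate = 0.1, seed = 11)
  g1 <- generate_activity_table(spec)
  g2 <- generate_activity_table(spec)
  expect_identical(g1, g2)
  spec2 <- spec; spec2$seed <- 12L
  g3 <- generate_activity_table(spec2)
  expect_false(identical(g1$table$standard_value, g3$table$standard_value))
  expect_identical(table(g1$ledger$rows$rule), table(g3$ledger$rows$rule))
})

test_that("impossible corruption combinations are rejected", {
  expect_error(table_corruption_spec(10, frac_censored_gt = 0.6,
                                     frac_censored_lt = 0.6),
               "sum to at most 1")
  expect_error(table_corruption_spec(10, frac_salts = 1.2), "\\[0, 1\\]")
  expect_error(generate_activity_table(
    table_corruption_spec(10, frac_censored_gt = 0.4, frac_censored_lt = 0.3,
                          frac_missing_value = 0.3, dup_rate = 0.3,
                          seed = 1)),
    "exceed the table size")
  expect_error(generate_activity_table(table_corruption_spec(5),
                                       smiles_pool = c("CCO", "C(((")),
               "invalid SMILES 'C\\(\\(\\('")
})

test_that("planted signal degenerates correctly without noise", {
  d0 <- generate_planted_dataset(
    planted_signal_spec(50, 20, 0, numeric(0), noise_sd = 0,
                        baseline = 5.5, seed = 4))
  expect_true(all(d0$activity == 5.5))

  d1 <- generate_planted_dataset(
    planted_signal_spec(80, 10, 1, 1.0, noise_sd = 0,
                        feature_kind = "binary", baseline = 5, seed = 5))
  expect_setequal(unique(d1$activity), c(5, 6))
  col <- d1$fingerprints$values[, d1$truth$informative]
  expect_equal(d1$activity, 5 + col, ignore_attr = TRUE)
})

test_that("least squares recovers the planted coefficients", {
  d <- generate_planted_dataset(
    planted_signal_spec(500, 100, 10, rep(0.5, 10), noise_sd = 0.3,
                        feature_kind = "count", seed = 6))
  X <- d$fingerprints$values[, d$truth$informative]
  fit <- lm(d$activity ~ X)
  expect_true(all(abs(coef(fit)[-1] - 0.5) < 0.1))
  expect_lt(abs(coef(fit)[1] - 5), 0.2)
})

test_that("planted generation validates its spec", {
  expect_error(planted_signal_spec(10, 5, 6, rep(1, 6)), "exceeds")
  expect_error(planted_signal_spec(10, 5, 2, c(1, 2, 3)), "length")
  expect_error(planted_signal_spec(10, 5, 1, 1, noise_sd = -1), ">= 0")
})

test_that("censored planted records are bounded one unit past the truth", {
  d <- planted_binary_study()
  cen <- generate_censored_planted(d$truth, n_gt = 30, n_lt = 30,
                                   bound_offset = 1, seed = 8)
  expect_equal(cen$gt$bound_pic50 - cen$gt$true_pic50, rep(1, 30))
  expect_equal(cen$lt$true_pic50 - cen$lt$bound_pic50, rep(1, 30))
  # a perfect oracle is always on the right side of the bound
  oracle <- function(X) d$truth$baseline +
    as.numeric(X[, d$truth$informative, drop = FALSE] %*%
                 d$truth$coefficients)
  rep <- censored_accuracy(oracle,
                           cen$gt$fingerprints$values, cen$gt$bound_pic50,
                           cen$lt$fingerprints$values, cen$lt$bound_pic50)
  expect_identical(rep$accuracy_gt, 1)
  expect_identical(rep$accuracy_lt, 1)
})

test_that("correlated feature draws share one distribution and are seeded", {
  X1 <- generate_correlated_features(100, 30, loading_seed = 9, seed = 1)
  X2 <- generate_correlated_features(100, 30, loading_seed = 9, seed = 1)
  X3 <- generate_correlated_features(100, 30, loading_seed = 9, seed = 2)
  expect_identical(X1, X2)
  expect_false(identical(X1, X3))
  expect_equal(dim(X1), c(100, 30))
  # low-rank structure: two PCs dominate
  ev <- prcomp(X1)$sdev^2
  expect_gt(sum(ev[1:2]) / sum(ev), 0.8)
})
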