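# Random-forest regression of pIC50: training, grid tuning, k-fold
# cross-validation, Gini-importance ranking and the top-k refit. The
# forest engine is ranger, run single-threaded with explicit seeds so
# every result is reproducible bit-for-bit.

#' Random-forest configuration
#'
#' @param n_trees number of trees.
#' @param max_features features considered per split: `"sqrt"`, `"third"`,
#'   or a positive integer.
#' @param min_samples_leaf minimal terminal-node size.
#' @param seed integer seed used when growing the forest.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, max_features = "sqrt",
                      min_samples_leaf = 1L, seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (is.numeric(max_features) && max_features < 1)
    stop("numeric max_features must be >= 1", call. = FALSE)
  if (is.character(max_features) &&
      !max_features %in% c("sqrt", "third"))
    stop("max_features must be 'sqrt', 'third' or a number", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 max_features = max_features,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Default hyperparameter grid
#'
#' @return named list of candidate values for [tune_rf()].
#' @export
default_tuning_grid <- function() {
  list(n_trees = c(100L, 500L),
       max_features = c("sqrt", "third"),
       min_samples_leaf = c(1L, 5L))
}

resolve_mtry <- function(max_features, p) {
  m <- if (identical(max_features, "sqrt")) sqrt(p)
       else if (identical(max_features, "third")) p / 3
       else as.numeric(max_features)
  max(1L, min(p, as.integer(floor(m))))
}

#' Regression performance: squared Pearson correlation and RMSE
#'
#' `r_squared` is the squared Pearson correlation between observed and
#' predicted values (the convention used for both the training R2 and the
#' cross-validated/external Q2 here); `rmse` is the root mean squared
#' error. `method = "press"` instead returns the 1 - SSres/SStot form of
#' the coefficient of determination.
#'
#' @param y_obs,y_pred equal-length numeric vectors, n >= 3.
#' @param method `"pearson"` (default) or `"press"`.
#' @return list with `r_squared` and `rmse`.
#' @export
evaluate <- function(y_obs, y_pred, method = c("pearson", "press")) {
  method <- match.arg(method)
  stopifnot(length(y_obs) == length(y_pred))
  if (length(y_obs) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(y_obs) == 0 || (method == "pearson" && sd(y_pred) == 0))
    stop("correlation undefined for constant vectors", call. = FALSE)
  r2 <- if (method == "pearson") {
    cor(y_obs, y_pred)^2
  } else {
    1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  }
  list(r_squared = r2, rmse = sqrt(mean((y_obs - y_pred)^2)))
}

as_feature_matrix <- function(X) {
  if (inherits(X, "fingerprint_matrix")) X <- X$values
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("F%04d", seq_len(ncol(X)))
  X
}

#' Train a random-forest regression model
#'
#' Bootstrap-sampled regression forest with impurity (Gini-style, variance
#' reduction for regression) importances, normalized to sum to one.
#'
#' @param X numeric feature matrix or [fingerprint_matrix()].
#' @param y numeric response (pIC50).
#' @param config an [rf_config()].
#' @return object of class `model_bundle`: the fitted forest, its config,
#'   the feature names, and normalized importances.
#' @export
train_rf <- function(X, y, config = rf_config()) {
  X <- as_feature_matrix(X)
  stopifnot(inherits(config, "rf_config"), nrow(X) == length(y))
  if (any(is.na(X)) || any(is.na(y)))
    stop("missing values in X or y", call. = FALSE)
  forest <- ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = config$n_trees,
    mtry = resolve_mtry(config$max_features, ncol(X)),
    min.node.size = config$min_samples_leaf,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1L)
  imp <- forest$variable.importance[colnames(X)]
  total <- sum(imp)
  imp <- if (total > 0) imp / total else
    stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X))
  structure(list(forest = forest, config = config,
                 feature_names = colnames(X),
                 gini_importances = imp),
            class = "model_bundle")
}

#' @export
predict.model_bundle <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model features: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  X <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  predict(object$forest, data = X, num.threads = 1L)$predictions
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %d-tree forest on %d features (mtry rule %s)\n",
              x$config$n_trees, length(x$feature_names),
              as.character(x$config$max_features)))
  invisible(x)
}

# Internal: one fold assignment, balanced fold sizes, seeded.
assign_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  if (n / folds < 2) stop("a fold would have fewer than 2 rows", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' k-fold cross-validation of a forest configuration
#'
#' Rows are partitioned into folds once (seeded); each fold is predicted by
#' a forest trained on the remaining folds, so every row is held out
#' exactly once. Q2 is computed on the pooled out-of-fold predictions.
#'
#' @param X feature matrix or [fingerprint_matrix()].
#' @param y numeric response.
#' @param config an [rf_config()].
#' @param folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param q2_method passed to [evaluate()].
#' @return list with `q2_cv`, `rmse_cv`, `fold_table` (per-fold sizes and
#'   RMSE), `oof_pred` and the fold assignment.
#' @export
cross_validate <- function(X, y, config = rf_config(), folds = 10L,
                           seed = 1L, q2_method = "pearson") {
  X <- as_feature_matrix(X)
  fold_id <- assign_folds(nrow(X), folds, seed)
  oof <- numeric(nrow(X))
  per_fold <- data.frame(fold = seq_len(folds), n = NA_integer_,
                         rmse = NA_real_)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, "cvfold", k)
    fit <- train_rf(X[!hold, , drop = FALSE], y[!hold], cfg_k)
    oof[hold] <- predict(fit, X[hold, , drop = FALSE])
    per_fold$n[k] <- sum(hold)
    per_fold$rmse[k] <- sqrt(mean((y[hold] - oof[hold])^2))
  }
  ev <- evaluate(y, oof, method = q2_method)
  list(q2_cv = ev$r_squared, rmse_cv = ev$rmse, fold_table = per_fold,
       oof_pred = oof, fold_id = fold_id)
}

#' Grid search over forest hyperparameters
#'
#' Exhaustive evaluation of the candidate grid by k-fold cross-validated
#' Q2, using one shared fold assignment so configurations are compared on
#' identical partitions. Ties are broken toward fewer trees, then smaller
#' resolved mtry, then larger leaves.
#'
#' @param X feature matrix or [fingerprint_matrix()].
#' @param y numeric response.
#' @param grid named list of candidate values (see
#'   [default_tuning_grid()]).
#' @param folds CV folds (default 10).
#' @param seed seed for fold assignment and tree growing.
#' @return the winning [rf_config()], with the full scored grid in
#'   attribute `"grid_scores"`.
#' @export
tune_rf <- function(X, y, grid = default_tuning_grid(), folds = 10L,
                    seed = 1L) {
  X <- as_feature_matrix(X)
  if (!length(grid)) stop("empty tuning grid", call. = FALSE)
  full <- list(n_trees = 500L, max_features = "sqrt",
               min_samples_leaf = 1L)
  full[names(grid)] <- grid
  combos <- expand.grid(i = seq_along(full$n_trees),
                        j = seq_along(full$max_features),
                        k = seq_along(full$min_samples_leaf))
  scores <- data.frame(n_trees = integer(0), max_features = character(0),
                       min_samples_leaf = integer(0), q2_cv = numeric(0))
  cv_seed <- derive_seed(seed, "tunefolds")
  for (r in seq_len(nrow(combos))) {
    cfg <- rf_config(full$n_trees[combos$i[r]],
                     full$max_features[[combos$j[r]]],
                     full$min_samples_leaf[combos$k[r]],
                     seed = derive_seed(seed, "tunefit", r))
    cv <- cross_validate(X, y, cfg, folds = folds, seed = cv_seed)
    scores <- rbind(scores, data.frame(
      n_trees = cfg$n_trees,
      max_features = as.character(cfg$max_features),
      min_samples_leaf = cfg$min_samples_leaf,
      q2_cv = cv$q2_cv, stringsAsFactors = FALSE))
  }
  scores$mtry <- vapply(scores$max_features, resolve_mtry, numeric(1),
                        p = ncol(X))
  ord <- order(-scores$q2_cv, scores$n_trees, scores$mtry,
               -scores$min_samples_leaf)
  best <- scores[ord[1L], ]
  mf <- best$max_features
  if (!mf %in% c("sqrt", "third")) mf <- as.numeric(mf)
  out <- rf_config(best$n_trees, mf, best$min_samples_leaf,
                   seed = derive_seed(seed, "final"))
  attr(out, "grid_scores") <- scores
  out
}

#' Rank features by Gini importance
#'
#' @param bundle a [train_rf()] model.
#' @param k number of top features (truncated with a warning when `k`
#'   exceeds the feature count).
#' @return data.frame (feature, importance), descending importance; ties
#'   broken by feature-name order.
#' @export
rank_features <- function(bundle, k = 20L) {
  stopifnot(inherits(bundle, "model_bundle"))
  imp <- bundle$gini_importances
  if (k > length(imp)) {
    warning("k exceeds the number of features; returning all")
    k <- length(imp)
  }
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord][seq_len(k)],
             importance = unname(imp[ord])[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Assemble a train/CV/external performance report
#'
#' @param y_train,pred_train training observations and predictions.
#' @param cv result of [cross_validate()] (or `NULL`).
#' @param y_ext,pred_ext external observations/predictions (or `NULL`).
#' @param q2_method passed to [evaluate()].
#' @return object of class `performance_report` with r2_train, rmse_train,
#'   q2_cv, rmse_cv, q2_ext, rmse_ext and `margin` (r2_train - q2_ext).
#' @export
performance_report <- function(y_train, pred_train, cv = NULL,
                               y_ext = NULL, pred_ext = NULL,
                               q2_method = "pearson") {
  tr <- evaluate(y_train, pred_train, method = q2_method)
  out <- list(r2_train = tr$r_squared, rmse_train = tr$rmse,
              q2_cv = NA_real_, rmse_cv = NA_real_,
              q2_ext = NA_real_, rmse_ext = NA_real_, margin = NA_real_)
  if (!is.null(cv)) {
    out$q2_cv <- cv$q2_cv
    out$rmse_cv <- cv$rmse_cv
  }
  if (!is.null(y_ext)) {
    ex <- evaluate(y_ext, pred_ext, method = q2_method)
    out$q2_ext <- ex$r_squared
    out$rmse_ext <- ex$rmse
    out$margin <- out$r2_train - out$q2_ext
  }
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("R2_Tr = %.3f  RMSE_Tr = %.3f  Q2_CV = %.3f  ",
                     "RMSE_CV = %.3f  Q2_Ext = %.3f  RMSE_Ext = %.3f  ",
                     "R2_Tr - Q2_Ext = %.3f\n"),
              x$r2_train, x$rmse_train, x$q2_cv, x$rmse_cv, x$q2_ext,
              x$rmse_ext, x$margin))
  invisible(x)
}

#' Refit on the top-k features
#'
#' Retrains the forest on the `k` most important features of a fitted
#' bundle and re-evaluates train, cross-validation and (optionally)
#' external performance identically to the full model.
#'
#' @param X,y training data used for the original fit.
#' @param bundle the fitted full [train_rf()] model.
#' @param k number of features retained (default 20).
#' @param X_ext,y_ext optional external partition.
#' @param folds,cv_seed cross-validation settings.
#' @param q2_method passed to [evaluate()].
#' @return list with `bundle` (the reduced model), `report`
#'   (a [performance_report()]) and `features` (the retained ranking).
#' @export
refit_top_k <- function(X, y, bundle, k = 20L, X_ext = NULL, y_ext = NULL,
                        folds = 10L, cv_seed = 1L, q2_method = "pearson") {
  X <- as_feature_matrix(X)
  top <- rank_features(bundle, k)
  # keep the original column order so k = ncol(X) reproduces the full fit
  Xk <- X[, colnames(X)[colnames(X) %in% top$feature], drop = FALSE]
  cfg <- bundle$config
  fit <- train_rf(Xk, y, cfg)
  cv <- cross_validate(Xk, y, cfg, folds = folds, seed = cv_seed,
                       q2_method = q2_method)
  pred_ext <- NULL
  if (!is.null(X_ext)) {
    X_ext <- as_feature_matrix(X_ext)
    pred_ext <- predict(fit, X_ext[, top$feature, drop = FALSE])
  }
  report <- performance_report(y, predict(fit, Xk), cv, y_ext, pred_ext,
                               q2_method = q2_method)
  list(bundle = fit, report = report, features = top)
}
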