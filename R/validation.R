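# Robustness battery: Y-scrambling, Golbraikh-Tropsha acceptability
# thresholds, the Eriksson chance-correlation margin, the PCA bounding-box
# applicability domain, and censored-label external accuracy.

#' Y-scrambling (response permutation) test
#'
#' Retrains the forest `n` times on permuted activities (X fixed) with the
#' tuned hyperparameters, recording the training R2 and cross-validated Q2
#' of every scrambled model next to the real one. The model is judged
#' robust when the real point clears the acceptability thresholds while
#' every scrambled Q2 stays below the Q2 threshold.
#'
#' @param X feature matrix or [fingerprint_matrix()].
#' @param y numeric response.
#' @param config the tuned [rf_config()] (not re-tuned per permutation).
#' @param n number of scrambles (default 100).
#' @param seed master seed for the permutations.
#' @param folds CV folds per model.
#' @param r2_threshold,q2_threshold acceptability thresholds (0.6 / 0.5).
#' @param q2_method passed to [evaluate()].
#' @return object of class `scrambling_report`: `real_point`,
#'   `scrambled_points` (data.frame r2_train, q2_cv), `n_scrambles`,
#'   `seed`, `verdict` (`"robust"` or `"chance_correlation"`).
#' @export
y_scramble <- function(X, y, config = rf_config(), n = 100L, seed = 1L,
                       folds = 10L, r2_threshold = 0.6, q2_threshold = 0.5,
                       q2_method = "pearson") {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  X <- as_feature_matrix(X)
  cv_seed <- derive_seed(seed, "scramblefolds")

  point <- function(y_k, fit_seed) {
    cfg <- config
    cfg$seed <- fit_seed
    fit <- train_rf(X, y_k, cfg)
    tr <- evaluate(y_k, predict(fit, X), method = q2_method)
    cv <- cross_validate(X, y_k, cfg, folds = folds, seed = cv_seed,
                         q2_method = q2_method)
    c(r2_train = tr$r_squared, q2_cv = cv$q2_cv)
  }

  real <- point(y, config$seed)
  pts <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("r2_train", "q2_cv")))
  for (k in seq_len(n)) {
    set.seed(derive_seed(seed, "scramble", k))
    y_perm <- y[sample(length(y))]
    pts[k, ] <- point(y_perm, derive_seed(seed, "scramblefit", k))
  }
  scrambled <- as.data.frame(pts)
  robust <- real["r2_train"] > r2_threshold &&
    real["q2_cv"] > q2_threshold &&
    all(scrambled$q2_cv < q2_threshold)
  structure(list(real_point = real,
                 scrambled_points = scrambled,
                 n_scrambles = n, seed = seed,
                 r2_threshold = r2_threshold,
                 q2_threshold = q2_threshold,
                 verdict = if (robust) "robust" else "chance_correlation"),
            class = "scrambling_report")
}

#' @export
print.scrambling_report <- function(x, ...) {
  cat(sprintf(paste0("Y-scrambling: real (R2 %.3f, Q2 %.3f); %d scrambles, ",
                     "max scrambled Q2 %.3f; verdict: %s\n"),
              x$real_point["r2_train"], x$real_point["q2_cv"],
              x$n_scrambles, max(x$scrambled_points$q2_cv), x$verdict))
  invisible(x)
}

#' Golbraikh-Tropsha acceptability thresholds
#'
#' A model is acceptable when R2 (training) exceeds 0.6 and Q2 exceeds 0.5,
#' both strictly.
#'
#' @param report a [performance_report()], or the training R2 as a number.
#' @param q2 the Q2 value when `report` is given as a number; with a
#'   report, the cross-validated Q2 is used (external Q2 when CV is
#'   absent).
#' @param r2_threshold,q2_threshold thresholds (defaults 0.6 and 0.5).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed thresholds, empty on pass).
#' @export
acceptability_check <- function(report, q2 = NULL, r2_threshold = 0.6,
                                q2_threshold = 0.5) {
  if (inherits(report, "performance_report")) {
    r2 <- report$r2_train
    q2 <- if (!is.na(report$q2_cv)) report$q2_cv else report$q2_ext
  } else {
    r2 <- as.numeric(report)
    if (is.null(q2)) stop("q2 required with numeric input", call. = FALSE)
  }
  reasons <- character(0)
  if (!(r2 > r2_threshold))
    reasons <- c(reasons, sprintf("R2 = %.3f not > %.2f", r2, r2_threshold))
  if (!(q2 > q2_threshold))
    reasons <- c(reasons, sprintf("Q2 = %.3f not > %.2f", q2, q2_threshold))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Eriksson chance-correlation margin
#'
#' The difference between the training R2 and the external Q2. Margins
#' at or below 0.2 indicate a predictive, reliable model; margins between
#' 0.2 and 0.3 warrant caution; larger margins suggest chance correlation
#' or outliers.
#'
#' @param report a [performance_report()], or the training R2 as a number.
#' @param q2_ext the external Q2 when `report` is numeric.
#' @return list with `margin` and `flag` (`"ok"`, `"warn"`, or
#'   `"chance_correlation_or_outliers"`).
#' @export
eriksson_margin <- function(report, q2_ext = NULL) {
  if (inherits(report, "performance_report")) {
    r2 <- report$r2_train
    q2_ext <- report$q2_ext
  } else {
    r2 <- as.numeric(report)
    if (is.null(q2_ext)) stop("q2_ext required", call. = FALSE)
  }
  margin <- r2 - q2_ext
  # tolerance absorbs decimal-arithmetic noise at the band edges
  flag <- if (margin <= 0.2 + 1e-9) "ok"
          else if (margin <= 0.3 + 1e-9) "warn"
          else "chance_correlation_or_outliers"
  list(margin = margin, flag = flag)
}

#' PCA bounding-box applicability domain
#'
#' Fits a PCA on the (scaled) training descriptor matrix only, projects
#' training and external compounds into score space, and flags an external
#' compound as inside the applicability domain when its score lies within
#' the training minimum-maximum box on every retained component.
#'
#' @param train_X scaled training matrix (the PCA is centred here; do not
#'   refit scalers on external data).
#' @param external_X scaled external matrix, same columns.
#' @param n_components number of principal components (default 2, a scores
#'   plot).
#' @return object of class `ad_report`: `n_components`,
#'   `train_score_bounds` (per-PC min/max), `external_scores`,
#'   `inside_flags`, `fraction_inside`.
#' @export
pca_bounding_box <- function(train_X, external_X, n_components = 2L) {
  train_X <- as_feature_matrix(train_X)
  external_X <- as_feature_matrix(external_X)
  if (n_components > min(dim(train_X)))
    stop("n_components exceeds the rank of the training matrix",
         call. = FALSE)
  missing <- setdiff(colnames(train_X), colnames(external_X))
  if (length(missing))
    stop("external matrix lacks features: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  external_X <- external_X[, colnames(train_X), drop = FALSE]
  pca <- prcomp(train_X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  tr_scores <- pca$x[, k, drop = FALSE]
  ex_scores <- predict(pca, external_X)[, k, drop = FALSE]
  bounds <- apply(tr_scores, 2, range)
  rownames(bounds) <- c("min", "max")
  inside <- vapply(seq_len(nrow(ex_scores)), function(i) {
    all(ex_scores[i, ] >= bounds["min", ] & ex_scores[i, ] <= bounds["max", ])
  }, logical(1))
  structure(list(n_components = as.integer(n_components),
                 train_score_bounds = bounds,
                 external_scores = ex_scores,
                 inside_flags = inside,
                 fraction_inside = mean(inside),
                 pca = pca),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("PCA bounding-box AD (%d PCs): %.1f%% of external compounds inside\n",
              x$n_components, 100 * x$fraction_inside))
  invisible(x)
}

#' Censored-label external accuracy
#'
#' Scores a regression model against records known only as IC50 bounds.
#' A `>`-censored record (IC50 greater than the bound: less potent than
#' the bound reads, true pIC50 below `bound_pic50`) counts as correct when
#' the predicted pIC50 falls strictly below its bound; a `<`-censored
#' record counts as correct when the prediction lies strictly above its
#' bound. Predictions exactly on the bound are incorrect.
#'
#' @param model a `model_bundle`, or any function mapping a feature matrix
#'   to predicted pIC50 (e.g. an oracle).
#' @param gt_X,gt_bound feature matrix and bound pIC50 vector of the
#'   `>`-censored set (`NULL` when absent).
#' @param lt_X,lt_bound same for the `<`-censored set.
#' @param transform optional function applied to each feature matrix
#'   before prediction (the fitted preprocessing pipeline).
#' @return object of class `censored_eval_report`: `n_gt`, `accuracy_gt`,
#'   `n_lt`, `accuracy_lt` (accuracy `NA` for an empty set) and
#'   `verdicts` (per-record data.frame).
#' @export
censored_accuracy <- function(model, gt_X = NULL, gt_bound = NULL,
                              lt_X = NULL, lt_bound = NULL,
                              transform = NULL) {
  predict_with <- function(X) {
    if (!is.null(transform)) X <- transform(X)
    if (is.function(model)) model(X) else predict(model, X)
  }
  score <- function(X, bound, relation) {
    if (is.null(X)) return(NULL)
    X <- as_feature_matrix(X)
    stopifnot(nrow(X) == length(bound))
    if (nrow(X) == 0L) return(NULL)
    pred <- predict_with(X)
    correct <- if (relation == ">") pred < bound else pred > bound
    data.frame(relation = relation, bound_pic50 = bound,
               predicted_pic50 = pred, correct = correct,
               stringsAsFactors = FALSE)
  }
  gt <- score(gt_X, gt_bound, ">")
  lt <- score(lt_X, lt_bound, "<")
  structure(list(
    n_gt = if (is.null(gt)) 0L else nrow(gt),
    accuracy_gt = if (is.null(gt)) NA_real_ else mean(gt$correct),
    n_lt = if (is.null(lt)) 0L else nrow(lt),
    accuracy_lt = if (is.null(lt)) NA_real_ else mean(lt$correct),
    verdicts = rbind(gt, lt)),
    class = "censored_eval_report")
}

#' @export
print.censored_eval_report <- function(x, ...) {
  cat(sprintf("censored accuracy: '>' %s (n = %d), '<' %s (n = %d)\n",
              ifelse(is.na(x$accuracy_gt), "absent",
                     sprintf("%.3f", x$accuracy_gt)), x$n_gt,
              ifelse(is.na(x$accuracy_lt), "absent",
                     sprintf("%.3f", x$accuracy_lt)), x$n_lt))
  invisible(x)
}
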