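# Descriptor preprocessing: zero-variance removal, two-stage pairwise
# correlation filtering, autoscaling fitted on training rows only, and
# repeated random 70/30 splits.

#' Remove constant descriptor columns
#'
#' @param matrix numeric matrix with column names.
#' @return list with `matrix` (columns with SD 0 removed) and `removed`
#'   (their names).
#' @export
drop_zero_variance <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  sds <- apply(matrix, 2, sd)
  removed <- colnames(matrix)[sds == 0]
  if (length(removed) == ncol(matrix))
    stop("all columns are constant; nothing to model", call. = FALSE)
  list(matrix = matrix[, sds > 0, drop = FALSE], removed = removed)
}

#' Pairwise correlation filter
#'
#' Stage 1: while any descriptor pair has |Pearson r| above
#' `pair_threshold`, the pair with the largest |r| is located and the
#' member with the larger mean absolute correlation to all remaining
#' descriptors is removed (ties: the later column). Stage 2 optionally
#' repeats the procedure at `secondary_threshold`. After filtering, every
#' retained pair satisfies |r| <= the active threshold.
#'
#' @param matrix numeric matrix, zero-variance columns already removed.
#' @param pair_threshold stage-1 absolute-correlation threshold.
#' @param secondary_threshold stage-2 threshold; `NULL` skips stage 2.
#' @return object of class `filter_result`: list with `retained`,
#'   `removed` (data.frame: feature, reason, partner, stage) and the
#'   thresholds.
#' @export
correlation_filter <- function(matrix, pair_threshold = 0.95,
                               secondary_threshold = 0.7) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  thr <- c(pair_threshold, secondary_threshold)
  if (any(thr <= 0 | thr > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  if (any(apply(matrix, 2, sd) == 0))
    stop("zero-variance columns must be removed first", call. = FALSE)

  removed <- data.frame(feature = character(0), reason = character(0),
                        partner = character(0), stage = integer(0),
                        stringsAsFactors = FALSE)
  prune <- function(X, threshold, stage) {
    repeat {
      if (ncol(X) < 2L) break
      cm <- abs(cor(X))
      diag(cm) <- 0
      mx <- max(cm)
      if (mx <= threshold) break
      idx <- which(cm == mx, arr.ind = TRUE)[1L, ]
      i <- min(idx); j <- max(idx)
      mean_i <- mean(cm[i, -i]); mean_j <- mean(cm[j, -j])
      drop_col <- if (mean_j >= mean_i) j else i
      partner <- if (drop_col == j) i else j
      removed <<- rbind(removed, data.frame(
        feature = colnames(X)[drop_col],
        reason = sprintf("|r| = %.4f > %.2f", mx, threshold),
        partner = colnames(X)[partner],
        stage = stage, stringsAsFactors = FALSE))
      X <- X[, -drop_col, drop = FALSE]
    }
    X
  }
  X <- prune(matrix, pair_threshold, 1L)
  active <- pair_threshold
  if (!is.null(secondary_threshold)) {
    X <- prune(X, secondary_threshold, 2L)
    active <- secondary_threshold
  }
  structure(list(retained = colnames(X), removed = removed,
                 pair_threshold = pair_threshold,
                 secondary_threshold = secondary_threshold,
                 active_threshold = active),
            class = "filter_result")
}

#' Fit an autoscaler (mean centring, unit variance)
#'
#' Means and sample standard deviations are estimated from the supplied
#' (training) rows only; apply the fitted scaler to external rows with
#' [apply_scaler()] rather than refitting.
#'
#' @param matrix numeric training matrix; no zero-variance columns.
#' @return object of class `scaler_model` (feature_names, means, sds).
#' @export
fit_scaler <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  sds <- apply(matrix, 2, sd)
  if (any(sds == 0))
    stop("zero-variance columns must be removed before scaling",
         call. = FALSE)
  structure(list(feature_names = colnames(matrix),
                 means = colMeans(matrix), sds = sds),
            class = "scaler_model")
}

#' Apply (or invert) a fitted autoscaler
#'
#' @param scaler a [fit_scaler()] model.
#' @param matrix numeric matrix whose columns are a superset of the
#'   scaler's features; columns are matched by name and returned in the
#'   scaler's feature order.
#' @param inverse undo the scaling instead.
#' @return scaled (or unscaled) matrix.
#' @export
apply_scaler <- function(scaler, matrix, inverse = FALSE) {
  stopifnot(inherits(scaler, "scaler_model"), is.matrix(matrix))
  missing <- setdiff(scaler$feature_names, colnames(matrix))
  if (length(missing))
    stop("matrix lacks features known to the scaler: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  X <- matrix[, scaler$feature_names, drop = FALSE]
  if (inverse) {
    sweep(sweep(X, 2, scaler$sds, `*`), 2, scaler$means, `+`)
  } else {
    sweep(sweep(X, 2, scaler$means, `-`), 2, scaler$sds, `/`)
  }
}

#' Repeated random 70/30 splits
#'
#' Each split is an independent uniform random partition of the ids at the
#' requested ratio, with the internal (training) size `round(ratio * n)`.
#' Split seeds are derived deterministically from `base_seed` and the split
#' index, so the full list is reproducible.
#'
#' @param ids character or integer vector of compound ids (n >= 10).
#' @param n_splits number of independent splits.
#' @param ratio fraction assigned to the internal set (default 0.70).
#' @param base_seed integer master seed.
#' @return list of `split_spec` objects (seed, ratio_internal,
#'   internal_ids, external_ids).
#' @export
make_splits <- function(ids, n_splits = 10L, ratio = 0.7, base_seed = 1L) {
  if (length(ids) < 10L) stop("need at least 10 ids", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  if (n_splits < 1L) stop("n_splits must be >= 1", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  n_int <- round(ratio * length(ids))
  lapply(seq_len(n_splits), function(k) {
    seed <- derive_seed(base_seed, "split", k)
    set.seed(seed)
    internal <- sort(sample(length(ids), n_int))
    structure(list(seed = seed, ratio_internal = ratio,
                   internal_ids = ids[internal],
                   external_ids = ids[-internal]),
              class = "split_spec")
  })
}
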