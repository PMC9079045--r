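# End-to-end orchestration: curate -> featurize -> preprocess -> split ->
# tune/train -> validate -> report, from a single config with one master
# seed. Every stage writes its outputs and a manifest entry (file hashes,
# seeds, row/column counts) under the output directory.

#' Pipeline run configuration
#'
#' Bundles every stage's settings behind one master seed. Seeds for splits,
#' CV folds, forests and scrambling are derived deterministically from
#' `master_seed`, so a fixed config reproduces the run bit-for-bit.
#'
#' @param activity_table path to a ChEMBL-style CSV/TSV (see
#'   [read_activity_table()]) or a data.frame of raw records.
#' @param output_dir directory for stage outputs (created if absent).
#' @param pattern_file SMARTS pattern file; `NULL` uses the bundled set.
#' @param curation a [curation_config()].
#' @param fingerprint_kind `"count"` or `"presence"`.
#' @param pair_threshold,secondary_threshold correlation-filter thresholds.
#' @param n_splits,split_ratio repeated-split settings (default 10 x 70/30).
#' @param tuning_grid hyperparameter grid ([default_tuning_grid()]), or an
#'   [rf_config()] to skip tuning.
#' @param cv_folds cross-validation folds.
#' @param top_k features kept in the reduced refit (default 20).
#' @param n_scrambles Y-scrambling permutations (default 100).
#' @param ad_components PCA components for the applicability domain.
#' @param master_seed integer seed governing the whole run.
#' @return object of class `run_config`.
#' @export
run_config <- function(activity_table, output_dir,
                       pattern_file = NULL,
                       curation = curation_config(),
                       fingerprint_kind = c("count", "presence"),
                       pair_threshold = 0.95, secondary_threshold = 0.7,
                       n_splits = 10L, split_ratio = 0.7,
                       tuning_grid = default_tuning_grid(),
                       cv_folds = 10L, top_k = 20L,
                       n_scrambles = 100L, ad_components = 2L,
                       master_seed = 1L) {
  fingerprint_kind <- match.arg(fingerprint_kind)
  if (is.character(activity_table) && !file.exists(activity_table))
    stop("activity table not found: ", activity_table, call. = FALSE)
  stopifnot(inherits(curation, "curation_config"))
  structure(list(activity_table = activity_table, output_dir = output_dir,
                 pattern_file = pattern_file, curation = curation,
                 fingerprint_kind = fingerprint_kind,
                 pair_threshold = pair_threshold,
                 secondary_threshold = secondary_threshold,
                 n_splits = as.integer(n_splits), split_ratio = split_ratio,
                 tuning_grid = tuning_grid, cv_folds = as.integer(cv_folds),
                 top_k = as.integer(top_k),
                 n_scrambles = as.integer(n_scrambles),
                 ad_components = as.integer(ad_components),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

manifest_entry <- function(stage, files, seed = NA_integer_, ...) {
  info <- list(...)
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  c(list(stage = stage, files = as.list(files), md5 = hashes, seed = seed),
    info)
}

#' Run the full QSAR pipeline
#'
#' Executes curation, featurization, preprocessing, repeated 70/30 splits,
#' tuning (on the first split's internal set), per-split training and
#' external validation, the top-k Gini refit, Y-scrambling, the PCA
#' bounding-box applicability domain and censored-label evaluation. All
#' tabular outputs are written to `config$output_dir` together with a JSON
#' manifest.
#'
#' @param config a [run_config()].
#' @return object of class `run_artifacts` (invisible components: curation
#'   result, fingerprints, filter result, per-split reports, tuned config,
#'   top-k ranking, validation reports, manifest).
#' @export
qsar_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  seed <- config$master_seed

  # --- curation -----------------------------------------------------------
  table <- if (is.character(config$activity_table))
    read_activity_table(config$activity_table) else config$activity_table
  cur <- curate(table, config$curation)
  if (nrow(cur$compounds) < 10L)
    stop("stage curate: fewer than 10 compounds survive curation",
         call. = FALSE)
  f_cur <- file.path(out, "curated_compounds.csv")
  write_curated(cur, f_cur, audit_path = file.path(out, "curation_audit.json"))
  manifest$curate <- manifest_entry(
    "curate", c(f_cur, file.path(out, "curation_audit.json")),
    n_input = nrow(table), n_compounds = nrow(cur$compounds),
    n_gt = nrow(cur$gt_set), n_lt = nrow(cur$lt_set))

  # --- featurization ------------------------------------------------------
  patterns <- if (is.null(config$pattern_file)) default_pattern_set()
    else load_pattern_set(config$pattern_file)
  fp <- featurize_dataset(cur$compounds, patterns,
                          kind = config$fingerprint_kind)
  f_fp <- file.path(out, "fingerprints.csv")
  write_fingerprint_matrix(fp, f_fp)
  manifest$featurize <- manifest_entry(
    "featurize", f_fp, n_compounds = length(fp$compound_ids),
    n_features = length(fp$feature_names),
    n_failed = length(attr(fp, "failed")))

  y_all <- cur$compounds$pic50[match(fp$compound_ids,
                                     sprintf("CMP%05d",
                                             seq_len(nrow(cur$compounds))))]
  names(y_all) <- fp$compound_ids

  # --- preprocessing: variance and correlation filters (dataset-level) ----
  zv <- drop_zero_variance(fp$values)
  flt <- correlation_filter(zv$matrix, config$pair_threshold,
                            config$secondary_threshold)
  X_all <- zv$matrix[, flt$retained, drop = FALSE]
  f_flt <- file.path(out, "filter_result.json")
  jsonlite::write_json(list(zero_variance = zv$removed,
                            removed = flt$removed,
                            retained = flt$retained),
                       f_flt, auto_unbox = TRUE, digits = NA)
  manifest$preprocess <- manifest_entry(
    "preprocess", f_flt, n_retained = length(flt$retained),
    n_zero_variance = length(zv$removed),
    n_correlated_removed = nrow(flt$removed))

  # --- splits -------------------------------------------------------------
  splits <- make_splits(rownames(X_all), config$n_splits,
                        config$split_ratio, derive_seed(seed, "splits"))

  # --- tuning on the first split's internal set ---------------------------
  first <- splits[[1L]]
  X1_raw <- X_all[first$internal_ids, , drop = FALSE]
  X1_raw <- X1_raw[, apply(X1_raw, 2, sd) > 0, drop = FALSE]
  sc1 <- fit_scaler(X1_raw)
  X1 <- apply_scaler(sc1, X1_raw)
  tuned <- if (inherits(config$tuning_grid, "rf_config")) config$tuning_grid
    else tune_rf(X1, y_all[first$internal_ids], config$tuning_grid,
                 folds = config$cv_folds, seed = derive_seed(seed, "tune"))
  manifest$tune <- manifest_entry(
    "tune", character(0), seed = derive_seed(seed, "tune"),
    n_trees = tuned$n_trees,
    max_features = as.character(tuned$max_features),
    min_samples_leaf = tuned$min_samples_leaf)

  # --- per-split training and validation ----------------------------------
  split_rows <- list(); refit_rows <- list()
  ad_fractions <- numeric(config$n_splits)
  first_objects <- NULL
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    Xtr_raw <- X_all[sp$internal_ids, , drop = FALSE]
    Xex_raw <- X_all[sp$external_ids, , drop = FALSE]
    keep <- apply(Xtr_raw, 2, sd) > 0
    sc <- fit_scaler(Xtr_raw[, keep, drop = FALSE])
    Xtr <- apply_scaler(sc, Xtr_raw)
    Xex <- apply_scaler(sc, Xex_raw)
    ytr <- y_all[sp$internal_ids]; yex <- y_all[sp$external_ids]
    cfg <- tuned; cfg$seed <- derive_seed(seed, "fit", s)
    fit <- train_rf(Xtr, ytr, cfg)
    cv <- cross_validate(Xtr, ytr, cfg, folds = config$cv_folds,
                         seed = derive_seed(seed, "cv", s))
    rep_full <- performance_report(ytr, predict(fit, Xtr), cv, yex,
                                   predict(fit, Xex))
    refit <- refit_top_k(Xtr, ytr, fit, config$top_k, Xex, yex,
                         folds = config$cv_folds,
                         cv_seed = derive_seed(seed, "cvtop", s))
    ad <- pca_bounding_box(Xtr, Xex, config$ad_components)
    ad_fractions[s] <- ad$fraction_inside
    as_row <- function(r) data.frame(
      split = s, r2_train = r$r2_train, rmse_train = r$rmse_train,
      q2_cv = r$q2_cv, rmse_cv = r$rmse_cv, q2_ext = r$q2_ext,
      rmse_ext = r$rmse_ext, margin = r$margin)
    split_rows[[s]] <- as_row(rep_full)
    refit_rows[[s]] <- as_row(refit$report)
    if (s == 1L)
      first_objects <- list(fit = fit, refit = refit, scaler = sc,
                            split = sp, ad = ad, Xtr = Xtr, ytr = ytr)
  }
  perf_full <- do.call(rbind, split_rows)
  perf_refit <- do.call(rbind, refit_rows)
  f_perf <- file.path(out, "performance_splits.csv")
  write.csv(rbind(cbind(model = "full", perf_full),
                  cbind(model = sprintf("top%d", config$top_k), perf_refit)),
            f_perf, row.names = FALSE)
  manifest$train <- manifest_entry("train", f_perf,
                                   seed = derive_seed(seed, "fit", 1L),
                                   n_splits = config$n_splits)

  # --- Y-scrambling on the first split ------------------------------------
  scr <- y_scramble(first_objects$Xtr, first_objects$ytr, tuned,
                    n = config$n_scrambles,
                    seed = derive_seed(seed, "scramble"),
                    folds = config$cv_folds)
  f_scr <- file.path(out, "y_scrambling.csv")
  write.csv(rbind(data.frame(kind = "real",
                             r2_train = scr$real_point["r2_train"],
                             q2_cv = scr$real_point["q2_cv"]),
                  cbind(kind = "scrambled", scr$scrambled_points)),
            f_scr, row.names = FALSE)
  manifest$scramble <- manifest_entry(
    "scramble", f_scr, seed = derive_seed(seed, "scramble"),
    n_scrambles = config$n_scrambles, verdict = scr$verdict)

  # --- censored-label evaluation (top-k model of the first split) ---------
  cens_rep <- NULL
  if (nrow(cur$gt_set) + nrow(cur$lt_set) > 0L) {
    top_features <- first_objects$refit$features$feature
    feat_cens <- function(df) {
      if (nrow(df) == 0L) return(NULL)
      fpz <- featurize_dataset(df, patterns, kind = config$fingerprint_kind,
                               ids = sprintf("CEN%05d", seq_len(nrow(df))))
      fpz$values
    }
    pipe <- function(Xn) {
      Xn <- Xn[, names(first_objects$scaler$means), drop = FALSE]
      apply_scaler(first_objects$scaler, Xn)[, top_features, drop = FALSE]
    }
    gtX <- feat_cens(cur$gt_set); ltX <- feat_cens(cur$lt_set)
    cens_rep <- censored_accuracy(first_objects$refit$bundle,
                                  gtX, cur$gt_set$bound_pic50,
                                  ltX, cur$lt_set$bound_pic50,
                                  transform = pipe)
    f_cens <- file.path(out, "censored_eval.csv")
    write.csv(cens_rep$verdicts, f_cens, row.names = FALSE)
    manifest$censored <- manifest_entry(
      "censored", f_cens, n_gt = cens_rep$n_gt, n_lt = cens_rep$n_lt)
  }

  f_man <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA)

  structure(list(config = config, curation = cur, fingerprints = fp,
                 filter = flt, splits = splits, tuned_config = tuned,
                 performance_full = perf_full,
                 performance_refit = perf_refit,
                 top_features = first_objects$refit$features,
                 scrambling = scr, ad_fractions = ad_fractions,
                 censored = cens_rep, manifest = manifest,
                 output_dir = out),
            class = "run_artifacts")
}

#' Human-readable pipeline summary
#'
#' Formats (a) the per-split performance table with mean and SD rows, (b)
#' the top-k feature importances, and (c) the validation verdicts
#' (acceptability, Eriksson flag, scrambling verdict, applicability-domain
#' fraction, censored accuracies).
#'
#' @param artifacts a [qsar_run()] result.
#' @param file optional path; when given the summary is also written there.
#' @return character vector of report lines, invisibly when printed.
#' @export
qsar_report <- function(artifacts, file = NULL) {
  stopifnot(inherits(artifacts, "run_artifacts"))
  x <- artifacts
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("QSAR pipeline report (master seed %d)", x$config$master_seed)
  add("compounds: %d curated, %d censored '>' / %d censored '<'",
      nrow(x$curation$compounds), nrow(x$curation$gt_set),
      nrow(x$curation$lt_set))
  add("features: %d retained of %d", length(x$filter$retained),
      length(x$fingerprints$feature_names))
  add("")
  add("Performance across %d splits (mean +/- SD):", nrow(x$performance_full))
  fmt_row <- function(df, label) {
    add("  %-8s R2_Tr %.2f+/-%.2f  RMSE_Tr %.2f+/-%.2f  Q2_CV %.2f+/-%.2f  Q2_Ext %.2f+/-%.2f  RMSE_Ext %.2f+/-%.2f  margin %.2f",
        label,
        mean(df$r2_train), sd(df$r2_train),
        mean(df$rmse_train), sd(df$rmse_train),
        mean(df$q2_cv), sd(df$q2_cv),
        mean(df$q2_ext), sd(df$q2_ext),
        mean(df$rmse_ext), sd(df$rmse_ext),
        mean(df$margin))
  }
  fmt_row(x$performance_full, "full")
  fmt_row(x$performance_refit, sprintf("top%d", x$config$top_k))
  add("")
  add("Top features (Gini importance):")
  for (i in seq_len(min(10L, nrow(x$top_features))))
    add("  %2d. %-28s %.4f", i, x$top_features$feature[i],
        x$top_features$importance[i])
  add("")
  mean_rep <- list(r2_train = mean(x$performance_full$r2_train),
                   q2_cv = mean(x$performance_full$q2_cv),
                   q2_ext = mean(x$performance_full$q2_ext))
  acc <- acceptability_check(mean_rep$r2_train, mean_rep$q2_cv)
  em <- eriksson_margin(mean_rep$r2_train, mean_rep$q2_ext)
  add("Validation verdicts:")
  add("  acceptability (R2 > 0.6, Q2 > 0.5): %s%s",
      ifelse(acc$pass, "pass", "FAIL"),
      ifelse(acc$pass, "", paste0(" [", paste(acc$reasons, collapse = "; "),
                                  "]")))
  add("  Eriksson margin: %.3f (%s)", em$margin, em$flag)
  add("  Y-scrambling: %s (max scrambled Q2 %.3f vs real %.3f)",
      x$scrambling$verdict, max(x$scrambling$scrambled_points$q2_cv),
      x$scrambling$real_point["q2_cv"])
  add("  applicability domain: %.1f%% of external compounds inside (mean over splits)",
      100 * mean(x$ad_fractions))
  if (!is.null(x$censored))
    add("  censored accuracy: '>' %s (n=%d), '<' %s (n=%d)",
        ifelse(is.na(x$censored$accuracy_gt), "absent",
               sprintf("%.2f", x$censored$accuracy_gt)), x$censored$n_gt,
        ifelse(is.na(x$censored$accuracy_lt), "absent",
               sprintf("%.2f", x$censored$accuracy_lt)), x$censored$n_lt)
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat(qsar_report(x), sep = "\n")
  invisible(x)
}
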