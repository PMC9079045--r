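# Synthetic bioactivity data with known ground truth.
#
# Two generators back the test suite and the examples: raw ChEMBL-style
# activity tables with controlled corruption (censoring, salts, replicate
# duplicates, missing values, off-target confidence/assay codes) plus a
# per-row ledger of the curation outcome they should produce; and
# fingerprint-like feature matrices with a planted linear signal.

#' Bundled pool of drug-like SMILES
#'
#' Reads the pool of pre-verified, drug-like structures shipped with the
#' package, used as default input for [generate_activity_table()].
#'
#' @return named character vector of SMILES (names are compound names).
#' @export
default_smiles_pool <- function() {
  path <- system.file("extdata", "smiles_pool.smi", package = "qsarflow",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1L)
  names(smi) <- vapply(parts, `[`, character(1), 2L)
  smi
}

#' Specification of a corrupted synthetic activity table
#'
#' Describes how many raw records to emit and which corruption each
#' fraction of them carries. Fractions are converted to row counts with
#' `round()`; the censored/missing fractions must sum to at most 1 and all
#' corruption categories are assigned to disjoint compounds.
#'
#' @param n_compounds number of distinct base compounds.
#' @param frac_censored_gt,frac_censored_lt fraction of compounds reported
#'   only as an IC50 bound (relation `>` resp. `<`).
#' @param frac_salts fraction of rows whose SMILES carries a counter-ion
#'   fragment (chloride, sodium or bromide).
#' @param frac_missing_value fraction of compounds with a missing IC50.
#' @param dup_rate fraction of compounds emitted as replicate groups.
#' @param dup_replicates rows per replicate group (>= 2).
#' @param dup_noise_sd replicate scatter on the pIC50 scale (multiplicative
#'   on the concentration scale).
#' @param frac_low_confidence fraction of compounds with confidence < 9.
#' @param frac_nonbinding_assay fraction with assay type other than `B`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `table_corruption_spec`.
#' @export
table_corruption_spec <- function(n_compounds,
                                  frac_censored_gt = 0,
                                  frac_censored_lt = 0,
                                  frac_salts = 0,
                                  frac_missing_value = 0,
                                  dup_rate = 0,
                                  dup_replicates = 2L,
                                  dup_noise_sd = 0.05,
                                  frac_low_confidence = 0,
                                  frac_nonbinding_assay = 0,
                                  seed = 1L) {
  fr <- c(frac_censored_gt = frac_censored_gt,
          frac_censored_lt = frac_censored_lt,
          frac_salts = frac_salts,
          frac_missing_value = frac_missing_value,
          dup_rate = dup_rate,
          frac_low_confidence = frac_low_confidence,
          frac_nonbinding_assay = frac_nonbinding_assay)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (frac_censored_gt + frac_censored_lt + frac_missing_value > 1)
    stop("censored and missing fractions must sum to at most 1",
         call. = FALSE)
  if (n_compounds < 1) stop("n_compounds must be positive", call. = FALSE)
  if (dup_replicates < 2) stop("dup_replicates must be >= 2", call. = FALSE)
  if (dup_noise_sd < 0) stop("dup_noise_sd must be >= 0", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 frac_censored_gt = frac_censored_gt,
                 frac_censored_lt = frac_censored_lt,
                 frac_salts = frac_salts,
                 frac_missing_value = frac_missing_value,
                 dup_rate = dup_rate,
                 dup_replicates = as.integer(dup_replicates),
                 dup_noise_sd = dup_noise_sd,
                 frac_low_confidence = frac_low_confidence,
                 frac_nonbinding_assay = frac_nonbinding_assay,
                 seed = as.integer(seed)),
            class = "table_corruption_spec")
}

SALT_FRAGMENTS <- c("[Na+]", "Cl", "[Br-]")

#' Generate a raw activity table with a ground-truth curation ledger
#'
#' Emits a ChEMBL-style activity table realizing the corruption fractions
#' of `spec` (rounded to the nearest row count), together with a ledger
#' stating for every row which curation rule should remove or divert it and
#' the compound set expected to survive curation with default settings.
#'
#' @param spec a [table_corruption_spec()].
#' @param smiles_pool character vector of valid single-fragment SMILES used
#'   as base structures. When `spec$n_compounds` exceeds the pool size,
#'   additional unique aliphatic alcohols are synthesized.
#' @param dedup_sd_threshold the pIC50 standard-deviation threshold the
#'   ledger assumes when predicting the fate of replicate groups (must
#'   match the [curation_config()] used downstream; default 1.0).
#' @return list with `table` (data.frame of raw records) and `ledger`
#'   (per-row rules, expected surviving compounds, expected censored sets).
#' @export
generate_activity_table <- function(spec, smiles_pool = default_smiles_pool(),
                                    dedup_sd_threshold = 1.0) {
  stopifnot(inherits(spec, "table_corruption_spec"))
  if (length(smiles_pool) == 0L) stop("smiles_pool is empty", call. = FALSE)
  validate_smiles(smiles_pool)

  n <- spec$n_compounds
  base <- unname(smiles_pool)
  if (n > length(base)) {
    extra <- paste0(strrep("C", seq_len(n - length(base))), "CO")
    base <- c(base, extra)
  }
  set.seed(spec$seed)
  base <- base[sample(length(base))][seq_len(n)]
  canon <- canonical_smiles(vapply(base, function(s) {
    frs <- smiles_fragments(s)
    frs[which.max(heavy_atom_count(frs))]
  }, character(1)))
  if (anyDuplicated(canon))
    stop("smiles_pool collapses to duplicate canonical structures",
         call. = FALSE)

  true_pic50 <- round(runif(n, 4, 9), 4)

  n_gt <- round(spec$frac_censored_gt * n)
  n_lt <- round(spec$frac_censored_lt * n)
  n_miss <- round(spec$frac_missing_value * n)
  n_lowc <- round(spec$frac_low_confidence * n)
  n_nonb <- round(spec$frac_nonbinding_assay * n)
  n_dup <- round(spec$dup_rate * n)
  if (n_gt + n_lt + n_miss + n_lowc + n_nonb + n_dup > n)
    stop("requested corruption fractions exceed the table size",
         call. = FALSE)

  ord <- sample(n)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    idx <- ord[seq_len(k)]
    ord <<- ord[-seq_len(k)]
    idx
  }
  idx_gt <- take(n_gt); idx_lt <- take(n_lt); idx_miss <- take(n_miss)
  idx_lowc <- take(n_lowc); idx_nonb <- take(n_nonb); idx_dup <- take(n_dup)

  rule <- rep("none", n)
  rule[idx_gt] <- "censored_gt"; rule[idx_lt] <- "censored_lt"
  rule[idx_miss] <- "missing_value"; rule[idx_lowc] <- "low_confidence"
  rule[idx_nonb] <- "nonbinding_assay"; rule[idx_dup] <- "duplicate_group"

  conf <- rep(9L, n); conf[idx_lowc] <- sample(0:8, n_lowc, replace = TRUE)
  atype <- rep("B", n); atype[idx_nonb] <- "F"
  relation <- rep("=", n)
  relation[idx_gt] <- ">"; relation[idx_lt] <- "<"

  rows <- vector("list", n)
  group_pic50 <- vector("list", n)
  for (i in seq_len(n)) {
    if (rule[i] == "duplicate_group") {
      eps <- rnorm(spec$dup_replicates, 0, spec$dup_noise_sd)
      pic <- true_pic50[i] + eps
      val <- 10^(9 - pic)
      group_pic50[[i]] <- pic
      rows[[i]] <- data.frame(compound = i,
                              standard_value = val,
                              standard_relation = "=",
                              stringsAsFactors = FALSE)
    } else {
      val <- if (rule[i] == "missing_value") NA_real_ else 10^(9 - true_pic50[i])
      group_pic50[[i]] <- true_pic50[i]
      rows[[i]] <- data.frame(compound = i,
                              standard_value = val,
                              standard_relation = relation[i],
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  i <- tab$compound

  smiles_out <- base[i]
  n_salt_rows <- round(spec$frac_salts * m)
  salt_rows <- sample(m, n_salt_rows)
  if (n_salt_rows > 0) {
    ions <- sample(SALT_FRAGMENTS, n_salt_rows, replace = TRUE)
    smiles_out[salt_rows] <- paste0(smiles_out[salt_rows], ".", ions)
  }

  table <- data.frame(
    molecule_id = sprintf("MOL%04d", i),
    canonical_smiles = smiles_out,
    standard_value = tab$standard_value,
    standard_units = "nM",
    standard_relation = tab$standard_relation,
    confidence_score = conf[i],
    assay_type = atype[i],
    assay_id = sprintf("ASSAY%02d", 1L + (i %% 5L)),
    stringsAsFactors = FALSE
  )

  row_rule <- rule[i]
  row_rule[row_rule == "duplicate_group"] <- "duplicate_replicate"
  row_rule[row_rule == "censored_gt"] <- "divert_gt"
  row_rule[row_rule == "censored_lt"] <- "divert_lt"

  surv <- vapply(seq_len(n), function(j) {
    if (rule[j] == "none") return(TRUE)
    if (rule[j] == "duplicate_group") {
      pic <- group_pic50[[j]]
      return(sd(pic) <= dedup_sd_threshold)
    }
    FALSE
  }, logical(1))
  exp_pic <- vapply(seq_len(n), function(j) median(group_pic50[[j]]),
                    numeric(1))

  ledger <- list(
    rows = data.frame(row = seq_len(m),
                      molecule_id = table$molecule_id,
                      rule = row_rule,
                      stringsAsFactors = FALSE),
    expected_compounds = data.frame(
      canonical_smiles = canon[surv],
      pic50 = exp_pic[surv],
      stringsAsFactors = FALSE),
    expected_gt = data.frame(
      canonical_smiles = canon[idx_gt],
      bound_pic50 = true_pic50[idx_gt],
      stringsAsFactors = FALSE),
    expected_lt = data.frame(
      canonical_smiles = canon[idx_lt],
      bound_pic50 = true_pic50[idx_lt],
      stringsAsFactors = FALSE),
    dedup_sd_threshold = dedup_sd_threshold,
    counts = c(n_compounds = n, n_rows = m, n_censored_gt = n_gt,
               n_censored_lt = n_lt, n_missing = n_miss,
               n_low_confidence = n_lowc, n_nonbinding = n_nonb,
               n_duplicate_groups = n_dup, n_salt_rows = n_salt_rows)
  )
  list(table = table, ledger = ledger)
}

#' Write a synthetic activity table and its ledger
#'
#' @param x the list returned by [generate_activity_table()].
#' @param table_path CSV destination for the activity table.
#' @param ledger_path optional JSON destination for the ledger.
#' @return invisibly `table_path`.
#' @export
write_activity_table <- function(x, table_path, ledger_path = NULL) {
  write.csv(x$table, table_path, row.names = FALSE)
  if (!is.null(ledger_path))
    jsonlite::write_json(x$ledger, ledger_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  invisible(table_path)
}

#' Specification of a planted-signal fingerprint dataset
#'
#' @param n_compounds,n_features matrix dimensions.
#' @param n_informative number of features carrying signal.
#' @param effect_sizes numeric vector of length `n_informative` (pIC50 per
#'   count or per bit).
#' @param noise_sd Gaussian noise on the activity, pIC50 units.
#' @param feature_kind `"count"` (Poisson features) or `"binary"`
#'   (Bernoulli(0.5)).
#' @param count_rate Poisson mean for count features.
#' @param baseline intercept, pIC50 units.
#' @param seed integer seed.
#' @return an object of class `planted_signal_spec`.
#' @export
planted_signal_spec <- function(n_compounds, n_features, n_informative,
                                effect_sizes, noise_sd = 0.3,
                                feature_kind = c("count", "binary"),
                                count_rate = 2, baseline = 5, seed = 1L) {
  feature_kind <- match.arg(feature_kind)
  if (n_informative > n_features)
    stop("n_informative exceeds n_features", call. = FALSE)
  if (length(effect_sizes) != n_informative)
    stop("effect_sizes must have length n_informative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (count_rate <= 0) stop("count_rate must be positive", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = noise_sd, feature_kind = feature_kind,
                 count_rate = count_rate, baseline = baseline,
                 seed = as.integer(seed)),
            class = "planted_signal_spec")
}

#' Generate a fingerprint matrix with a planted linear signal
#'
#' Features are drawn iid (Poisson for counts, Bernoulli(0.5) for bits);
#' the activity is `baseline + X[, informative] %*% effect_sizes + noise`.
#' The informative columns are chosen (seeded) at random.
#'
#' @param spec a [planted_signal_spec()].
#' @return list with `fingerprints` (a `fingerprint_matrix`), `activity`
#'   (numeric vector) and `truth` (informative feature names, coefficients,
#'   baseline, generating spec).
#' @export
generate_planted_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_signal_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds; p <- spec$n_features
  X <- if (spec$feature_kind == "count") {
    matrix(rpois(n * p, spec$count_rate), n, p)
  } else {
    matrix(rbinom(n * p, 1L, 0.5), n, p)
  }
  fn <- sprintf("FP%03d", seq_len(p))
  colnames(X) <- fn
  ids <- sprintf("CPD%04d", seq_len(n))
  rownames(X) <- ids
  inf_idx <- sort(sample(p, spec$n_informative))
  y <- spec$baseline +
    as.numeric(X[, inf_idx, drop = FALSE] %*% spec$effect_sizes) +
    rnorm(n, 0, spec$noise_sd)
  fp <- fingerprint_matrix(X, kind = if (spec$feature_kind == "count")
    "count" else "presence", provenance = "synthetic")
  list(fingerprints = fp,
       activity = y,
       truth = list(informative = fn[inf_idx],
                    coefficients = stats::setNames(spec$effect_sizes,
                                                   fn[inf_idx]),
                    baseline = spec$baseline,
                    spec = spec))
}

#' Generate censored external records from a planted-signal truth
#'
#' Draws new compounds from the same feature distribution as the planted
#' dataset, computes their true activity from the planted coefficients, and
#' reports each one only as an IC50 bound placed `bound_offset` pIC50 units
#' past the true activity: `>`-censored records get `bound_pic50 =
#' true + bound_offset` (the compound is less potent than the bound reads),
#' `<`-censored records get `bound_pic50 = true - bound_offset`.
#'
#' @param truth the `truth` element of [generate_planted_dataset()].
#' @param n_gt,n_lt number of records per censoring sign.
#' @param bound_offset distance between the bound and the true activity,
#'   pIC50 units (default 1).
#' @param seed integer seed.
#' @return list with `gt` and `lt`, each holding `fingerprints`,
#'   `bound_pic50` and `true_pic50`.
#' @export
generate_censored_planted <- function(truth, n_gt = 100L, n_lt = 100L,
                                      bound_offset = 1, seed = 1L) {
  spec <- truth$spec
  set.seed(as.integer(seed))
  draw <- function(k, sign) {
    if (k == 0L) return(NULL)
    X <- if (spec$feature_kind == "count") {
      matrix(rpois(k * spec$n_features, spec$count_rate), k)
    } else {
      matrix(rbinom(k * spec$n_features, 1L, 0.5), k)
    }
    colnames(X) <- sprintf("FP%03d", seq_len(spec$n_features))
    rownames(X) <- sprintf("%s%04d", if (sign > 0) "GT" else "LT", seq_len(k))
    true <- spec$baseline +
      as.numeric(X[, truth$informative, drop = FALSE] %*%
                   truth$coefficients)
    list(fingerprints = fingerprint_matrix(
           X, kind = if (spec$feature_kind == "count") "count" else
             "presence", provenance = "synthetic"),
         bound_pic50 = true + sign * bound_offset,
         true_pic50 = true)
  }
  list(gt = draw(as.integer(n_gt), +1), lt = draw(as.integer(n_lt), -1))
}

#' Generate correlated fingerprint-like descriptor matrices
#'
#' Real fingerprint blocks are strongly collinear: related substructures
#' co-occur, so a few latent dimensions dominate the variance. This sampler
#' draws descriptor matrices from a low-rank factor model
#' `X = F L' + E` with fixed loadings `L` (so repeated draws share one
#' distribution), mimicking that structure for applicability-domain
#' studies.
#'
#' @param n number of compounds to draw.
#' @param p number of descriptors.
#' @param n_factors latent dimensions (default 2).
#' @param noise_sd residual standard deviation around the factor plane.
#' @param loading_seed seed fixing the loading matrix (the "distribution").
#' @param seed seed for this draw.
#' @return numeric matrix with compound/feature dimnames.
#' @export
generate_correlated_features <- function(n, p, n_factors = 2L,
                                         noise_sd = 0.3,
                                         loading_seed = 1L, seed = 1L) {
  set.seed(as.integer(loading_seed))
  L <- matrix(rnorm(p * n_factors), p, n_factors)
  set.seed(as.integer(seed))
  FF <- matrix(rnorm(n * n_factors), n, n_factors)
  X <- FF %*% t(L) + matrix(rnorm(n * p, 0, noise_sd), n, p)
  dimnames(X) <- list(sprintf("CPD%05d", seq_len(n)),
                      sprintf("FP%03d", seq_len(p)))
  X
}
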