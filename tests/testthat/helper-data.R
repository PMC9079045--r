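# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Planted count-fingerprint regression study: 600 compounds, 120 Poisson
# count features, 15 informative with effects 0.4-0.8, noise 0.4 pIC50.
planted_count_study <- function() {
  memo_fixture("planted_count", generate_planted_dataset(
    planted_signal_spec(600, 120, 15,
                        effect_sizes = seq(0.4, 0.8, length.out = 15),
                        noise_sd = 0.4, feature_kind = "count",
                        count_rate = 2, baseline = 5, seed = 101)))
}

# Presence-fingerprint study for censored-label evaluation: binary
# features keep the activity range commensurate with a 1-unit bound.
planted_binary_study <- function() {
  memo_fixture("planted_binary", generate_planted_dataset(
    planted_signal_spec(600, 60, 10, effect_sizes = rep(0.6, 10),
                        noise_sd = 0.2, feature_kind = "binary",
                        baseline = 6, seed = 303)))
}

# Forest configuration used for the validation batteries (scrambling runs
# retrain it 100 x 11 times, so it is kept lean).
battery_config <- function(seed = 3L) rf_config(100L, "third", 5L, seed = seed)

# Substructure counts for the bundled pool, via the package implementation.
pool_counts <- function() {
  memo_fixture("pool_counts", {
    pool <- default_smiles_pool()
    can <- canonical_smiles(unname(pool))
    list(smiles = can,
         counts = substructure_count(can, default_pattern_set()))
  })
}

# Small activity-table fixture shared by curation/pipeline tests.
small_table_fixture <- function() {
  memo_fixture("small_table", generate_activity_table(
    table_corruption_spec(40, frac_censored_gt = 0.1,
                          frac_censored_lt = 0.05, frac_salts = 0.15,
                          frac_missing_value = 0.05, dup_rate = 0.1,
                          dup_replicates = 3, dup_noise_sd = 0.05,
                          frac_low_confidence = 0.1,
                          frac_nonbinding_assay = 0.05, seed = 7)))
}
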