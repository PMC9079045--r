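# qsarflow

Random-forest QSAR modelling of bioactivity data with substructure
fingerprints, in R.

Drug-discovery groups that mine ChEMBL-style bioactivity tables — for
example IC50 measurements against estrogen receptor alpha (ERα), a major
breast-cancer target — face the same chain of chores before any modelling
can start: messy activity records must be filtered and deduplicated,
counter-ions stripped, concentrations converted to pIC50, structures turned
into descriptor vectors, and the resulting regression model defended
against chance correlation. qsarflow packages that whole chain as tested R
functions, for computational chemists and cheminformaticians who want a
reproducible, auditable pipeline rather than a pile of one-off scripts.

## The method

Each curated compound gets one potency value
`pIC50 = −log10(IC50 [mol/L])` and a descriptor vector of SMARTS
substructure **counts** (or presence bits): entry *j* is the number of
distinct atom sets matching pattern *j*. A random-forest regressor is
fitted under repeated 70/30 internal/external splits, with exhaustive grid
tuning by 10-fold cross-validation. Performance is reported as the squared
Pearson correlation between observed and predicted pIC50 — R²(Tr) on
training, Q²(CV) on pooled out-of-fold predictions, Q²(Ext) on the
held-out 30% — plus RMSE on each partition.

Robustness battery:

* **Acceptability**: R² > 0.6 and Q² > 0.5 (both strict).
* **Eriksson margin**: R²(Tr) − Q²(Ext); ≤ 0.2 reliable, 0.2–0.3 caution,
  above that chance correlation or outliers.
* **Y-scrambling**: 100 retrains on permuted labels; the model is robust
  only if every scrambled Q² stays below threshold while the real model
  passes.
* **Applicability domain**: PCA bounding box fitted on the training
  scores; external compounds outside the per-component min–max box are
  flagged.
* **Censored-label accuracy**: records known only as bounds (`IC50 > x`
  or `< x`) score a prediction correct when it falls strictly on the right
  side of the bound — an external check that needs no exact labels.
* **Gini feature ranking** and a top-20 refit guard against overfitting to
  a wide descriptor block.

A synthetic-data module generates corrupted activity tables with a
row-level ground-truth ledger (which curation rule should hit each row)
and planted-signal fingerprint datasets, so the entire pipeline is testable
offline with known truth.

## Worked example

Simulate a raw ChEMBL-style extract, run the full pipeline, read the
report:

```r
library(qsarflow)

spec <- table_corruption_spec(
  n_compounds = 150, frac_censored_gt = 0.10, frac_censored_lt = 0.05,
  frac_salts = 0.20, frac_missing_value = 0.05, dup_rate = 0.10,
  dup_replicates = 3, frac_low_confidence = 0.10,
  frac_nonbinding_assay = 0.05, seed = 42)
raw <- generate_activity_table(spec)
write_activity_table(raw, "activity_table.csv")

cfg <- run_config("activity_table.csv", output_dir = "qsar_run",
                  n_splits = 5, n_scrambles = 20,
                  tuning_grid = rf_config(100, "third", 5, seed = 1),
                  master_seed = 2026)
art <- qsar_run(cfg)
cat(qsar_report(art), sep = "\n")
```

```
QSAR pipeline report (master seed 2026)
compounds: 96 curated, 15 censored '>' / 8 censored '<'
features: 20 retained of 43

Performance across 5 splits (mean +/- SD):
  full     R2_Tr 0.51+/-0.05  RMSE_Tr 1.12+/-0.08  Q2_CV 0.02+/-0.03  Q2_Ext 0.04+/-0.05  RMSE_Ext 1.46+/-0.19  margin 0.46
  top20    R2_Tr 0.51+/-0.05  RMSE_Tr 1.12+/-0.08  Q2_CV 0.03+/-0.05  Q2_Ext 0.04+/-0.05  RMSE_Ext 1.46+/-0.19  margin 0.46

Top features (Gini importance):
   1. secondary_carbon             0.4480
   2. aliphatic_hydroxyl           0.1315
   3. c_ons_bond                   0.1066
   ...

Validation verdicts:
  acceptability (R2 > 0.6, Q2 > 0.5): FAIL [R2 = 0.507 not > 0.60; Q2 = 0.024 not > 0.50]
  Eriksson margin: 0.462 (chance_correlation_or_outliers)
  Y-scrambling: chance_correlation (max scrambled Q2 0.116 vs real 0.066)
  applicability domain: 96.6% of external compounds inside (mean over splits)
  censored accuracy: '>' 0.60 (n=15), '<' 0.88 (n=8)
```

Reading the report: 150 simulated compounds curate down to 96 unique
structures (censored, low-confidence, non-binding, missing-value and
disagreeing-replicate records removed or diverted, exactly as the
generator's ledger predicts). The simulated activities are random with
respect to structure, and every verdict says so — Q² near zero, margin in
the chance-correlation band, scrambled models indistinguishable from the
real one. The pipeline refusing to bless noise is the correct outcome.

On data that *does* carry signal, the same machinery passes. A
planted-signal study (600 compounds, 120 count features, 15 of them
informative, noise 0.4 pIC50):

```r
study <- generate_planted_dataset(planted_signal_spec(
  n_compounds = 600, n_features = 120, n_informative = 15,
  effect_sizes = seq(0.4, 0.8, length.out = 15), noise_sd = 0.4,
  feature_kind = "count", seed = 101))
X <- study$fingerprints$values; y <- study$activity
cfg <- rf_config(500, "sqrt", 1, seed = 3)
fit <- train_rf(X, y, cfg)
cv  <- cross_validate(X, y, cfg, folds = 10, seed = 8)
performance_report(y, predict(fit, X), cv)
#> R2_Tr = 0.995  RMSE_Tr = 0.972  Q2_CV = 0.700  RMSE_CV = 2.662 ...
acceptability_check(0.995, 0.700)$pass
#> TRUE
sum(study$truth$informative %in% rank_features(fit, 20)$feature)
#> 15   # all planted features recovered in the top 20
```

Individual stages are plain functions — `curate()`, `desalt()`,
`to_pic50()`, `load_pattern_set()`, `substructure_count()`,
`ro5_profile()`, `correlation_filter()`, `make_splits()`, `tune_rf()`,
`y_scramble()`, `pca_bounding_box()`, `censored_accuracy()` — and can be
used independently of the orchestrated run.

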