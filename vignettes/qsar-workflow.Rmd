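---
title: "Modelling pIC50 from substructure fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pIC50 from substructure fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarflow)
```

qsarflow implements a complete ligand-based QSAR workflow for estrogen
receptor alpha (ERα)-style bioactivity data: curation of raw ChEMBL-type
IC50 records into one pIC50 value per unique structure, SMARTS substructure
fingerprints, descriptor preprocessing, random-forest regression under
repeated 70/30 splits, and a robustness battery. This vignette explains the
model and the design decisions; the README shows a worked example.

## The modelling problem

Each compound $i$ carries a potency label on the log scale,
$\mathrm{pIC50}_i = -\log_{10} \mathrm{IC50}_i$ (IC50 in mol/L), and a
descriptor vector $x_i$ of substructure counts or presence bits obtained by
SMARTS matching. A random-forest regressor $\hat f$ is fitted to predict
pIC50 from $x$. Performance is summarized by the squared Pearson
correlation between observed and predicted values — $R^2_{Tr}$ on the
training (resubstitution) predictions, $Q^2_{CV}$ on pooled 10-fold
out-of-fold predictions, $Q^2_{Ext}$ on a held-out 30% external set — and
by RMSE on each partition. A model is *acceptable* when $R^2 > 0.6$ and
$Q^2 > 0.5$ (both strict); the margin $R^2_{Tr} - Q^2_{Ext}$ flags chance
correlation when it exceeds the 0.2–0.3 band.

$Q^2$ here is the squared Pearson correlation, not the
$1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ form; the two differ under
miscalibrated predictions. Both are available in `evaluate()` via
`method = c("pearson", "press")`; Pearson-squared is the default because it
is the quantity the acceptability thresholds refer to in this workflow.

## Curation

`curate()` composes four stages, each auditable row by row:

1. **Filtering** (`filter_records()`). Records must have relation `=`,
   confidence score 9 (direct single-protein assignment) and assay type
   `B` (binding). Records with `<`/`>` relations that pass the
   confidence/assay filters are *diverted*, not discarded: they form the
   `>`- and `<`-censored qualification sets used later for inequality
   validation. Missing and non-positive concentrations are dropped.
   Every removed row carries the first rule that fired.
2. **Desalting** (`desalt()`). Multi-fragment SMILES keep the fragment
   with the most heavy atoms; ties fall back to larger molecular weight,
   then the lexicographically smallest canonical SMILES. Counter-ions
   (chloride, sodium, bromide in the synthetic tables) never survive.
3. **Unit conversion** (`to_pic50()`). pIC50 = unit exponent −
   log10(value); nM is always accepted, and
   `unit_policy = "convert_known_units"` adds pM/µM/M. The strict default
   errors on anything else because silent unit mix-ups are the dominant
   curation failure mode.
4. **Deduplication** (`deduplicate()`). Records are grouped by exact
   canonical SMILES equality after desalting. A replicate group collapses
   to its **median** pIC50 when the group's standard deviation is at or
   below `dedup_sd_threshold`; otherwise the whole group is removed as a
   value disagreement. The published description of this rule ("greater
   than 2 SD", with the median used otherwise) does not state what
   quantity 2 SD bounds, nor on which scale; we read it as an absolute
   bound on the replicate pIC50 SD with a configurable threshold
   defaulting to 1.0 pIC50 units — deterministic, order-free, and in line
   with common ChEMBL curation practice. Statistics are computed on the
   log (pIC50) scale, where assay replicates scatter approximately
   symmetrically.

Stereochemistry is preserved through canonicalization: specified chiral
centres are themselves a descriptor (`graph_descriptors()`), so stripping
stereo would destroy a feature the downstream model ranks.

Two OpenBabel quirks shaped the implementation. Its SMILES reader silently
truncates syntactically broken input, so every entry point first runs a
small tokenizer (`validate_smiles()`) that checks balanced branches and
bracket atoms, paired ring-closure digits and legal atom symbols, and
rejects offending strings by name. And its SDF container cannot hold
single-heavy-atom species such as `[Na+]`, so molecular properties flow
through the lower-level molecule API instead.

## Featurization

`substructure_count()` reports, for each SMARTS pattern, the number of
**distinct matched atom sets** — symmetry-equivalent mappings of the same
atoms count once, so a benzene ring contains six `cc` bonds, not twelve.
Presence fingerprints are the indicator `count > 0`. The package bundles a
~40-pattern functional-group set covering the chemotype classes that
dominate ERα structure–activity analyses (phenols/catechols, amines,
aromatics, carboxylic-acid derivatives, ethers, tautomerizable motifs,
halogens); the full 307-pattern functional-group classification list is an
external artifact that loads through the same `load_pattern_set()` format.
Descriptor classes with no SMARTS expression — specified chiral centres and
rotatable bonds — are native graph operations in `graph_descriptors()`.

`standardize_molecule()` offers two optional normalizations: explicit
polar hydrogens (materialized on N/O/S from computed implicit counts) and
canonical tautomer selection. The tautomer normalizer handles the acyclic
1,3 keto-enol case (enols rewrite to ketones); aromatic and ring bonds are
never touched, so phenols survive. This is deliberately minimal: exhaustive
tautomer canonicalization is toolkit-specific, and the bundled pattern set
includes the 1,3-tautomerizable SMARTS so the motif remains countable
without rewriting.

Rule-of-five profiles (`ro5_profile()`) use the classic conventions:
donors are N–H plus O–H hydrogens, acceptors are N plus O atom counts, and
`violations` counts failures among MW < 500, logP < 5, HBA < 10, HBD ≤ 5.
The HBD rule is sometimes printed with the inequality reversed in the
applied literature; the canonical ≤ 5 direction is used here. logP is
OpenBabel's additive atomic-contribution estimate.

## Preprocessing and splitting

Zero-variance descriptors are removed first, then a two-stage pairwise
correlation filter: while any descriptor pair exceeds the threshold in
|Pearson r|, the pair with the largest |r| is located and the member with
the larger mean absolute correlation to the remaining descriptors is
dropped (ties: the later column). Stage one runs at 0.95; a second stage at
0.7 follows by default. Two printed thresholds without a stated second role
admit several readings; the two-stage pairwise filter reproduces both
numbers, and stage two can be disabled (`secondary_threshold = NULL`).
After filtering, every retained pair satisfies |r| ≤ the active threshold —
a property the tests verify by brute force.

Autoscaling (mean centring, unit variance, sample SD) is fitted on the
internal (training) rows of each split only and applied unchanged to
external rows: refitting a scaler on external data leaks information into
external validation. The variance and correlation filters, by contrast,
run once at dataset level — they mirror the published per-fingerprint
descriptor reductions, and Pearson correlation between descriptors does
not involve the response, so the leakage concern is minor there.

`make_splits()` draws independent uniform 70/30 partitions, seeds derived
from one base seed; the pipeline default is 10 splits with mean ± SD
reporting, since the published number of repeats is unstated.

## Random forest, tuning, and the top-20 refit

The forest engine is `ranger`, run single-threaded with explicit seeds so
every number in a report is bit-reproducible. The task is regression
(pIC50 is continuous, and the headline metrics are R²/RMSE), although the
source workflow names a classifier routine; regression forests are the
consistent reading. Tuning is an exhaustive grid — default
`n_trees ∈ {100, 500}`, `max_features ∈ {√p, p/3}`,
`min_samples_leaf ∈ {1, 5}` — scored by 10-fold CV Q² on one shared fold
assignment, ties broken toward fewer trees, then smaller mtry. Gini
(impurity) importances are normalized to sum to one, and `refit_top_k()`
retrains on the 20 most important features, re-evaluating train/CV/external
identically. Columns keep their original order in the refit so that
`k = p` reproduces the full model exactly.

## Validation battery

**Y-scrambling** (`y_scramble()`): the response is permuted `n = 100`
times, the forest retrained per permutation with the *fixed* tuned
hyperparameters (re-tuning per permutation would be 100× costlier and
would blur what is being tested: the label assignment), recording
(R²_train, Q²_CV) per scramble. The verdict is `robust` only when the real
point clears the acceptability thresholds and every scrambled Q² stays
below the Q² threshold.

**Applicability domain** (`pca_bounding_box()`): PCA is fitted on the
scaled training matrix only; training and external compounds are projected
and an external compound is inside the domain when its score lies within
the training min–max box on every retained component. Two components
reproduce a scores-plot reading; more components tighten the box. A box
can only flag a shift whose energy is visible inside the retained
components: each extra component also excludes a small fraction of
legitimate compounds (about `2k/(n+1)` for `k` components and `n` training
rows), so `k` trades detection power against false alarms. The shipped
applicability-domain study uses 30 scaled count descriptors (a typical
post-filter width), 1000 training compounds and 12 components, where a
+5 SD shift on ten descriptors concentrates enough energy per component to
be rejected (≤ 20% inside) while a same-distribution external set stays
admitted (≥ 95% inside). On wide descriptor blocks (hundreds of columns)
the same sparse shift spreads its energy so thin that *no* component count
achieves both at once — and on strongly collinear blocks (see
`generate_correlated_features()`) a shift orthogonal to the dominant
factors lands on components whose training ranges are sampling noise, so
verdicts become loading-seed lotteries. Both blindness regimes are
inherent to bounding-box domains and worth knowing before relying on one.

**Censored-label accuracy** (`censored_accuracy()`): a `>`-censored record
(IC50 above the bound, i.e. *less* potent than the bound reads) is
predicted correctly when the model places its pIC50 strictly below the
bound; a `<`-censored record when strictly above. Predictions exactly on a
bound count as wrong. The directionality is resolved on the pIC50 scale by
potency logic: IC50 > bound ⟺ pIC50 < bound. The synthetic censored study
uses *presence-type* (binary) planted fingerprints (600 compounds, 60
bits, 10 informative with effect 0.6, noise 0.2), whose activity range is
commensurate with the 1-unit bound offset; on wide-range count signals the
forest's residual spread exceeds one pIC50 unit and no honest model clears
a 1-unit inequality reliably — the evaluation would measure the signal
range, not the inequality logic.

## What the synthetic data does and does not emulate

`generate_activity_table()` produces raw tables with exact-value and
censored records, salt-bearing SMILES, replicate groups with multiplicative
concentration noise (additive in pIC50, N(0, 0.05) by default), missing
values and off-target confidence/assay codes, together with a row-level
ledger of the curation outcome each row should have — the curation oracle.
Activities are uniform on pIC50 4–9, the span typical of ChEMBL ERα IC50
data. The bundled 55-structure pool is drug-like and ERα-flavoured
(estradiol, tamoxifen, diethylstilbestrol, bisphenol A, genistein, common
drugs); when a table needs more distinct structures than the pool holds,
unique aliphatic alcohols fill the remainder.

`generate_planted_dataset()` plants a linear signal in iid Poisson count
or Bernoulli presence features. What passing tests show: the pipeline's
statistics, selection and validation logic behave correctly on data whose
truth is known. What they do not show: performance on real chemistry —
real activities are not linear in counts, real descriptors are correlated
and scaffold-clustered, and real assay noise is heteroscedastic. Synthetic
table activities are structure-independent by design (the ledger, not the
chemistry, is the target), so pipeline runs on them correctly return
`chance_correlation`.

## Numerical choices and degenerate inputs

* Unit conversion uses decimal exponents (`9 - log10(value)` for nM), so
  the anchors 1000 nM → 6.0 and 1 nM → 9.0 are exact in floating point.
* Correlation-filter tie-breaks and ranking tie-breaks (feature-name
  order) are deterministic, making every selection order-stable.
* `fit_scaler()` refuses zero-variance columns rather than dividing by
  zero; per-split constant columns are re-checked because a 70% subset of
  a near-constant descriptor can lose all variance.
* All-constant matrices, empty pattern sets, fold counts exceeding rows,
  and `n_components` above the training rank raise immediate errors.
* Forest importances that sum to zero (constant response) fall back to a
  uniform vector so the sum-to-one invariant holds.
* Seeds: one master seed drives named, deterministic child seeds for
  splits, folds, forests and scrambles (`derive_seed()`), all below 2³¹.

## Problem sizes used in the shipped studies

The test and acceptance studies run at 600 compounds × 120 count features
(15 informative, effects 0.4–0.8, noise 0.4) for the regression battery,
600 × 60 binary features for the censored study, 1000 + 200 compounds × 30
count descriptors with 12 components for the applicability domain, 100
scrambles, 50 random curation regimes of up to 200 compounds, and the
55-molecule pool × 43 patterns for fingerprint checks. These sizes give stable verdicts with
comfortable statistical margins while keeping a full run in minutes on one
CPU.

## Known limitations

* Aromaticity, canonical SMILES and logP follow OpenBabel's models; other
  toolkits (RDKit, CDK) differ on edge cases such as tautomer-rich
  heterocycles, so absolute counts for exotic patterns can differ across
  toolkits even when both are internally consistent.
* The tautomer normalizer covers acyclic 1,3 keto-enol pairs only.
* Only the substructure count/presence families are computed natively;
  the other fingerprint families (MACCS, PubChem, Klekota–Roth, ...) enter
  through `import_external_matrix()`.
* The bounding-box applicability domain is blind to shifts orthogonal to
  the retained components (demonstrated above) and to density holes inside
  the box; leverage- or distance-based domains are out of scope.
* Assay-format stratification of censored sets is not implemented; the
  `assay_id` is carried through so users can stratify downstream.
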