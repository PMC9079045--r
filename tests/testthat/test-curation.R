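make_record <- function(relation = "=", conf = 9L, atype = "B",
                        value = 100, smiles = "CCO", id = "M1",
                        units = "nM", assay = "A1") {
  data.frame(molecule_id = id, canonical_smiles = smiles,
             standard_value = value, standard_units = units,
             standard_relation = relation, confidence_score = conf,
             assay_type = atype, assay_id = assay,
             stringsAsFactors = FALSE)
}

test_that("filter_records partitions rows by the first firing rule", {
  tab <- rbind(make_record("=", 9, "B", 100),
               make_record(">", 9, "B", 1000),
               make_record("=", 8, "B", 50),
               make_record("=", 9, "F", 50),
               make_record("=", 9, "B", NA))
  f <- filter_records(tab)
  expect_equal(nrow(f$kept), 1)
  expect_equal(nrow(f$censored), 1)
  expect_equal(nrow(f$dropped), 3)
  expect_setequal(f$dropped$drop_rule,
                  c("confidence", "assay_type", "missing_value"))
  expect_equal(nrow(f$kept) + nrow(f$censored) + nrow(f$dropped), nrow(tab))
})

test_that("filter_records handles empty and all-clean tables", {
  empty <- make_record()[0, ]
  f0 <- filter_records(empty)
  expect_equal(vapply(f0, nrow, integer(1)),
               c(kept = 0L, censored = 0L, dropped = 0L))
  clean <- rbind(make_record(value = 10), make_record(value = 20, id = "M2"))
  f1 <- filter_records(clean)
  expect_equal(f1$kept, clean)
  expect_equal(nrow(f1$censored), 0)
  # unknown relation symbols go to the audit, not an abort
  odd <- make_record("~")
  expect_equal(filter_records(odd)$dropped$drop_rule, "unknown_relation")
})

test_that("desalting keeps the largest fragment in canonical form", {
  expect_identical(desalt("CC(=O)O.[Na+]"), canonical_smiles("CC(=O)O"))
  expect_identical(desalt("c1ccccc1"), canonical_smiles("c1ccccc1"))
  expect_identical(desalt("Cl.NCCc1ccccc1"), canonical_smiles("NCCc1ccccc1"))
  expect_length(smiles_fragments(desalt("CC(=O)O.[Na+]")), 1L)
  expect_error(desalt("C((("), "invalid SMILES")
  expect_error(desalt("[H+].[H+]"), "zero heavy atoms")
})

test_that("pIC50 conversion matches its definition and round-trips", {
  expect_identical(to_pic50(1000, "nM"), 6.0)
  expect_identical(to_pic50(1, "nM"), 9.0)
  expect_equal(to_pic50(50, "nM"), 9 - log10(50), tolerance = 1e-12)
  expect_equal(to_pic50(50, "nM"), 7.30103, tolerance = 1e-5)
  expect_error(to_pic50(0, "nM"), "non-positive")
  expect_error(to_pic50(-5, "nM"), "non-positive")
  expect_error(to_pic50(NA_real_, "nM"), "missing")
  expect_error(to_pic50(100, "uM"), "unrecognized units")
  expect_equal(to_pic50(1, "uM", "convert_known_units"), 6.0)
  expect_equal(to_pic50(1, "M", "convert_known_units"), 0.0)
  expect_equal(pic50_to_value(to_pic50(123.4, "nM")), 123.4,
               tolerance = 1e-12)
})

test_that("deduplication collapses agreeing groups and drops disagreeing ones", {
  rec <- function(s, p) data.frame(canonical_smiles = s, pic50 = p,
                                   molecule_id = "M", assay_id = "A",
                                   stringsAsFactors = FALSE)
  one <- deduplicate(rec("CCO", 6.0))
  expect_equal(one$compounds$pic50, 6.0)
  expect_equal(one$compounds$n_source_records, 1L)

  grp <- deduplicate(do.call(rbind, lapply(c(6.0, 6.1, 6.2), rec, s = "CCO")))
  expect_equal(nrow(grp$compounds), 1)
  expect_equal(grp$compounds$pic50, 6.1)   # median; sd = 0.1 <= 1.0

  bad <- deduplicate(do.call(rbind, lapply(c(5.0, 9.0), rec, s = "CCO")))
  expect_equal(nrow(bad$compounds), 0)
  expect_true(all(bad$removed$drop_rule == "value disagreement"))
  # sd of two points is |diff| / sqrt(2) ~ 2.83 > 1.0
  expect_gt(sd(c(5, 9)), 1)

  expect_error(deduplicate(rec("CCO", Inf)), "non-finite")
})

test_that("curate reproduces the generator ledger on mixed corruption", {
  g <- small_table_fixture()
  res <- curate(g$table)
  expect_setequal(res$compounds$canonical_smiles,
                  g$ledger$expected_compounds$canonical_smiles)
  m <- merge(res$compounds, g$ledger$expected_compounds,
             by = "canonical_smiles")
  expect_equal(m$pic50.x, m$pic50.y, tolerance = 1e-9)
  expect_setequal(res$gt_set$canonical_smiles,
                  g$ledger$expected_gt$canonical_smiles)
  expect_setequal(res$lt_set$canonical_smiles,
                  g$ledger$expected_lt$canonical_smiles)
  # partition: every input row is accounted for exactly once, either as a
  # source record of a surviving compound, a censored record, or an audit
  # entry naming the rule that removed it
  expect_equal(sum(res$compounds$n_source_records) + nrow(res$gt_set) +
                 nrow(res$lt_set) + nrow(res$audit),
               nrow(g$table))
})

test_that("curation is idempotent and order-invariant", {
  g <- small_table_fixture()
  res <- curate(g$table)
  # idempotence: re-expressing the curated set as a table changes nothing
  tab2 <- data.frame(molecule_id = sprintf("R%04d",
                                           seq_len(nrow(res$compounds))),
                     canonical_smiles = res$compounds$canonical_smiles,
                     standard_value = pic50_to_value(res$compounds$pic50),
                     standard_units = "nM", standard_relation = "=",
                     confidence_score = 9L, assay_type = "B",
                     assay_id = "RE", stringsAsFactors = FALSE)
  res2 <- curate(tab2)
  expect_equal(sort(res2$compounds$canonical_smiles),
               sort(res$compounds$canonical_smiles))
  expect_equal(res2$compounds$pic50[order(res2$compounds$canonical_smiles)],
               res$compounds$pic50[order(res$compounds$canonical_smiles)],
               tolerance = 1e-9)
  # order invariance
  set.seed(1)
  res3 <- curate(g$table[sample(nrow(g$table)), ])
  expect_equal(res3$compounds, res$compounds)
})

test_that("a table of only censored records diverts everything", {
  tab <- rbind(make_record(">", value = 1000, smiles = "CCO", id = "M1"),
               make_record(">", value = 500, smiles = "CCCO", id = "M2"),
               make_record("<", value = 10, smiles = "CCCCO", id = "M3"))
  res <- curate(tab)
  expect_equal(nrow(res$compounds), 0)
  expect_equal(nrow(res$gt_set), 2)
  expect_equal(nrow(res$lt_set), 1)
  expect_equal(res$gt_set$bound_pic50, c(6, 9 - log10(500)))
})

test_that("adding a droppable row never removes surviving compounds", {
  g <- small_table_fixture()
  res <- curate(g$table)
  extra <- make_record("=", conf = 3L, smiles = "CCOCC", id = "MX")
  res2 <- curate(rbind(g$table, extra))
  expect_equal(res2$compounds, res$compounds)
  expect_equal(nrow(res2$audit), nrow(res$audit) + 1)
})

test_that("curated tables round-trip through the CSV writers", {
  g <- small_table_fixture()
  tf <- tempfile(fileext = ".csv")
  write_activity_table(g, tf, ledger_path = tempfile(fileext = ".json"))
  back <- read_activity_table(tf)
  expect_equal(nrow(back), nrow(g$table))
  expect_equal(back$canonical_smiles, g$table$canonical_smiles)

  res <- curate(back)
  out <- tempfile(fileext = ".csv")
  sdf <- tempfile(fileext = ".sdf")
  write_curated(res, out, sdf_path = sdf)
  expect_true(file.exists(out) && file.exists(sdf))
  reread <- read.csv(out)
  expect_equal(reread$pic50, res$compounds$pic50, tolerance = 1e-9)
})
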