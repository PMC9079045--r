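test_that("pattern sets load in order and reject bad input", {
  tf <- tempfile(fileext = ".smarts")
  writeLines(c("# comment", "phenol\t[OX2H]c", "amine [NX3]",
               "", "acid\t[CX3](=O)[OX2H]"), tf)
  ps <- load_pattern_set(tf)
  expect_s3_class(ps, "pattern_set")
  expect_identical(ps$name, c("phenol", "amine", "acid"))

  writeLines(c("ok\tC", "bad\tC((("), tf)
  expect_error(load_pattern_set(tf), "line 2.*does not compile")
  writeLines(c("dup\tC", "dup\tN"), tf)
  expect_error(load_pattern_set(tf), "duplicate feature names")
  writeLines("onlyname", tf)
  expect_error(load_pattern_set(tf), "expected 'name SMARTS'")

  expect_gt(nrow(default_pattern_set()), 30)
})

test_that("substructure counts match hand-derived cases", {
  ps <- default_pattern_set()
  m <- substructure_count(c("Oc1ccccc1", "Oc1ccccc1O", "c1ccccc1"), ps)
  expect_identical(unname(m[, "phenol"]), c(1L, 2L, 0L))
  expect_identical(unname(m[, "catechol"]), c(0L, 1L, 0L))
  expect_identical(unname(m[, "primary_amine"]), c(0L, 0L, 0L))
  expect_identical(unname(m[, "aromatic_carbon"]), c(6L, 6L, 6L))
})

test_that("presence bits threshold the counts", {
  expect_identical(substructure_presence(c(0, 2, 1)), c(0L, 1L, 1L))
  expect_identical(substructure_presence(matrix(0, 2, 3)),
                   matrix(0L, 2, 3))
  expect_error(substructure_presence(c(1, -1)), "negative")
  pc <- pool_counts()
  expect_true(all(substructure_presence(pc$counts) == (pc$counts > 0)))
})

test_that("featurize_dataset keeps shape, order and determinism", {
  ps <- default_pattern_set()
  smi <- c("CCO", "Oc1ccccc1")
  fp <- featurize_dataset(smi, ps, ids = c("a", "b"))
  expect_s3_class(fp, "fingerprint_matrix")
  expect_equal(dim(fp$values), c(2, nrow(ps)))
  expect_identical(fp$compound_ids, c("a", "b"))
  fp2 <- featurize_dataset(smi, ps, ids = c("a", "b"))
  expect_identical(fp$values, fp2$values)
  # rare elements absent from both molecules are flagged zero-variance
  expect_true(all(c("iodine", "phosphorus") %in% attr(fp, "zero_variance")))
  # broken SMILES are excluded and reported, not fatal
  fp3 <- featurize_dataset(c("CCO", "C(((", "Oc1ccccc1"), ps,
                           ids = c("a", "bad", "b"))
  expect_identical(attr(fp3, "failed"), "bad")
  expect_identical(fp3$compound_ids, c("a", "b"))
  expect_error(featurize_dataset("CCO", default_pattern_set()[0, ]),
               "empty pattern set|pattern_set")
})

test_that("standardization options are no-ops when disabled", {
  sdf0 <- parse_smiles("Oc1ccccc1", ids = "mol")
  std0 <- standardize_molecule("Oc1ccccc1")
  expect_identical(std0[[1]]@atomblock, sdf0[[1]]@atomblock)
  expect_identical(std0[[1]]@bondblock, sdf0[[1]]@bondblock)
})

test_that("polar hydrogens become explicit graph atoms", {
  std <- standardize_molecule("Oc1ccccc1", add_polar_h = TRUE)
  el <- sub("_.*", "", rownames(std[[1]]@atomblock))
  expect_equal(sum(el == "H"), 1)
  # the new hydrogen is bonded to the oxygen
  bb <- std[[1]]@bondblock
  hrow <- which(el == "H")
  expect_true(any((bb[, 1] == hrow & el[bb[, 2]] == "O") |
                  (bb[, 2] == hrow & el[bb[, 1]] == "O")))
  # amide N-H and carbonyl O: only N gains a hydrogen
  std2 <- standardize_molecule("CC(=O)NC", add_polar_h = TRUE)
  el2 <- sub("_.*", "", rownames(std2[[1]]@atomblock))
  expect_equal(sum(el2 == "H"), 1)
})

test_that("1,3 keto-enol pairs normalize to one canonical tautomer", {
  can <- function(s) canonical_smiles(as.character(ChemmineR::sdf2smiles(
    standardize_molecule(s, canonical_tautomer = TRUE))))
  expect_identical(can("CC(O)=C"), can("CC(C)=O"))     # propen-2-ol / acetone
  expect_identical(can("OC(=CC)C"), can("CCC(C)=O"))   # butenol / butanone
  # aromatic hydroxyls are not ketonized
  expect_identical(can("Oc1ccccc1"), canonical_smiles("Oc1ccccc1"))
})

test_that("rule-of-five profiles follow the classic conventions", {
  r <- ro5_profile(c("CCO", "Nc1ccccc1", "OCC(O)CO"))
  expect_equal(r$hbd, c(1, 2, 3))
  expect_equal(r$hba, c(1, 1, 3))
  expect_equal(r$violations, c(0, 0, 0))
  expect_equal(r$mw[1], 46.07, tolerance = 1e-3)

  expect_identical(ro5_violations(600, 6.0, 2, 8), 2L)
  expect_identical(ro5_violations(300, 2.0, 2, 5), 0L)
  expect_identical(ro5_violations(501, 5.1, 6, 11), 4L)
  # monotone in each property, others fixed
  expect_true(all(diff(ro5_violations(c(100, 499, 500, 900), 1, 1, 1)) >= 0))
  expect_true(all(diff(ro5_violations(300, c(-1, 4.9, 5, 8), 1, 1)) >= 0))
  expect_true(all(diff(ro5_violations(300, 1, c(0, 5, 6, 9), 1)) >= 0))
  expect_true(all(diff(ro5_violations(300, 1, 1, c(0, 9, 10, 12))) >= 0))
})

test_that("graph descriptors count stereocentres and rotatable bonds", {
  g <- graph_descriptors(c("N[C@@H](Cc1ccc(O)cc1)C(=O)O",  # tyrosine
                           "CCCCO", "CC(C)(C)C", "c1ccccc1"))
  expect_identical(g$chiral_centers, c(1L, 0L, 0L, 0L))
  expect_identical(g$rotatable_bonds[2], 2L)   # butanol: C-C-C-C-O
  expect_identical(g$rotatable_bonds[4], 0L)   # ring bonds never rotate
})

test_that("external matrices import, validate and round-trip", {
  tf <- tempfile(fileext = ".csv")
  df <- data.frame(id = c("a", "b", "c"), f1 = 1:3, f2 = c(0, 2, 4),
                   f3 = c(1, 1, 0), f4 = 0:2)
  write.csv(df, tf, row.names = FALSE)
  fp <- import_external_matrix(tf, "count")
  expect_equal(dim(fp$values), c(3, 4))
  expect_identical(fp$provenance, "external")

  out <- tempfile(fileext = ".csv")
  write_fingerprint_matrix(fp, out)
  fp2 <- import_external_matrix(out, "count")
  expect_equal(fp$values, fp2$values)
  expect_identical(fp$compound_ids, fp2$compound_ids)

  df$f2[2] <- NA
  write.csv(df, tf, row.names = FALSE)
  expect_error(import_external_matrix(tf), "row 2, column 'f2'")
  df$f2[2] <- 2; df$id[2] <- "a"
  write.csv(df, tf, row.names = FALSE)
  expect_error(import_external_matrix(tf), "duplicate")
})
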