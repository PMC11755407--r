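test_that("molecule tables parse with explicit rejection reporting", {
  f <- write_temp_csv(data.frame(
    id = c("m1", "m2", "m3", "m4"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)NC", "C1CC"),
    label = c("active", "inactive", "inactive", "active")))
  res <- parse_molecule_table(f, "csv")
  expect_equal(nrow(res$records), 3L)
  expect_equal(nrow(res$rejects), 1L)
  expect_equal(res$rejects$id, "m4")
  expect_match(res$rejects$reason, "unparseable")
  expect_setequal(res$records$label, c("active", "inactive"))
})

test_that("unknown label tokens are an error, not a silent coercion", {
  f <- write_temp_csv(data.frame(id = "m1", smiles = "CCO", label = "maybe"))
  expect_error(parse_molecule_table(f, "csv"), "unknown label token")
})

test_that("SMILES files parse with positional ids", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "c1ccccc1"), f)
  res <- parse_molecule_table(f)
  expect_equal(res$records$id[1], "eth")
  expect_equal(nrow(res$records), 2L)
})

test_that("standardization strips salts, fixes tautomers, and is idempotent", {
  s <- standardize_smiles(c("c1ccccc1.[Na+].[Cl-]", "C1=CC=CC=C1"))
  expect_equal(s[1], "c1ccccc1")
  expect_equal(s[2], "c1ccccc1")
  # keto and enol forms of the same molecule map to one canonical tautomer
  pair <- standardize_smiles(c("CC(O)=CC", "CCC(C)=O"))
  expect_equal(pair[1], pair[2])
  # aromatic hydroxyls are left alone
  expect_equal(standardize_smiles("Oc1ccccc1"), "Oc1ccccc1")
  # idempotence over a sample of generated molecules
  ds <- fx_dataset_clean()
  sm <- ds$records$smiles[seq(1, 400, by = 10)]
  once <- standardize_smiles(sm)
  expect_identical(standardize_smiles(once), once)
})

test_that("pure salts signal an empty structure", {
  recs <- parse_molecule_table(
    write_temp_csv(data.frame(id = "s", smiles = "[Na+].[Cl-]", label = "inactive")),
    "csv")
  expect_error(standardize_records(recs$records), "empty structure")
})

test_that("deduplication is stereo-aware and order-independent", {
  recs <- standardize_records(parse_molecule_table(write_temp_csv(data.frame(
    id = c("a1", "a2", "e1", "e2", "c1", "c2"),
    smiles = c("CCO", "OCC",                      # same molecule
               "C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O",  # enantiomers
               "c1ccccc1C", "Cc1ccccc1"),        # duplicate with label clash
    label = c("active", "active", "active", "inactive", "active", "inactive"))),
    "csv")$records)
  dd <- deduplicate_records(recs)
  # ethanol collapsed, enantiomer pair kept distinct, toluene conflicted
  expect_equal(sort(dd$records$id), c("a1", "e1", "e2"))
  expect_length(dd$conflicts, 1L)
  expect_setequal(dd$conflicts[[1]]$id, c("c1", "c2"))
  # permuting the input yields the same surviving InChI set
  dd2 <- deduplicate_records(recs[sample(nrow(recs)), ])
  expect_setequal(dd$records$inchi, dd2$records$inchi)
})

test_that("conflict policies resolve as documented", {
  grp <- data.frame(id = c("x1", "x2", "x3"),
                    smiles = "Cc1ccccc1", inchi = "InChI=1S/x",
                    label = c("active", "inactive", "inactive"),
                    source = "literature", assay_note = "",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(resolve_conflicts(list(grp), "drop")), 0L)
  expect_equal(resolve_conflicts(list(grp), "majority")$label, "inactive")
  expect_equal(resolve_conflicts(list(grp), "prefer_active")$label, "active")
  expect_match(resolve_conflicts(list(grp), "majority")$assay_note, "majority")
  expect_error(resolve_conflicts(list(grp), "coin_flip"))
})

test_that("splits are stratified, deterministic and arithmetically consistent", {
  ds <- fx_dataset_clean()
  s1 <- split_dataset(ds$records, test_fraction = 0.1, seed = 5)
  s2 <- split_dataset(ds$records, test_fraction = 0.1, seed = 5)
  expect_identical(s1$train, s2$train)
  expect_identical(s1$test1, s2$test1)
  expect_length(intersect(s1$train, s1$test1), 0L)
  expect_equal(length(s1$train) + length(s1$test1), nrow(ds$records))
  # both classes present in the test partition across many seeds
  labs <- setNames(ds$records$label, ds$records$id)
  for (seed in 1:25) {
    s <- split_dataset(ds$records, test_fraction = 0.1, seed = seed)
    expect_gte(sum(labs[s$test1] == "active"), 1L)
  }
  # nested carve: test2 comes out of the training pool
  s3 <- split_dataset(ds$records, test_fraction = 0.1, seed = 5,
                      carve_test2 = 50L)
  expect_length(intersect(s3$test2, s3$test1), 0L)
  expect_equal(length(s3$train) + length(s3$test2) + length(s3$test1),
               nrow(ds$records))
  # explicit per-class counts are honoured exactly
  s4 <- split_dataset(ds$records, seed = 2,
                      counts = list(test1 = c(active = 3, inactive = 37)))
  expect_equal(sum(labs[s4$test1] == "active"), 3L)
  expect_length(s4$test1, 40L)
  expect_error(split_dataset(ds$records[ds$records$label == "inactive", ],
                             seed = 1), "both activity classes")
})
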