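screen_fixture <- function() {
  fixture("screen_fx", function() {
    ds <- fx_dataset_clean()
    fps <- fx_fps_clean()
    sm <- setNames(ds$records$smiles, ds$records$id)
    cm <- prune_to_x(cluster_dataset(fps, smiles = sm), fps, smiles = sm)
    feats <- fps  # model trained on the same fingerprint family
    model <- qsar_train(feats, ds$records$label, family = "rf",
                        n_trees = 300, seed = 13)
    lib <- generate_screen_library(n_total = 120, n_hits_planted = 2,
                                   n_unrelated = 20, seed = 31)
    lib_fps <- fp_morgan(lib$records$smiles, ids = lib$records$id)
    list(ds = ds, fps = fps, cm = cm, model = model, lib = lib,
         lib_fps = lib_fps)
  })
}

test_that("screening applies the probability-AND-domain rule", {
  fx <- screen_fixture()
  hits <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                         smiles = setNames(fx$lib$records$smiles,
                                           fx$lib$records$id))
  expect_equal(nrow(hits), 120L)
  expect_true(all(hits$passed == (hits$p_active >= 0.64 & hits$in_ad)))
  # planted actives rank at the top by predicted probability
  planted <- names(fx$lib$truth)[fx$lib$truth == "active"]
  expect_true(all(match(planted, hits$id) <= 5))
  # a molecule above the probability bar but outside the domain never passes
  above_out <- hits$p_active >= 0.64 & !hits$in_ad
  expect_true(all(!hits$passed[above_out]))
})

test_that("the cluster centroids themselves are always in-domain", {
  fx <- screen_fixture()
  cent_ids <- vapply(fx$cm$centroids, function(ct) ct$id, character(1))
  res <- in_applicability_domain(fx$fps[cent_ids, , drop = FALSE], fx$cm)
  expect_true(all(res$in_ad))
  expect_true(all(res$max_similarity == 1))
})

test_that("screening is monotone in the probability threshold and AD-consistent", {
  fx <- screen_fixture()
  h64 <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                        config = screening_config(p_threshold = 0.64))
  h80 <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                        config = screening_config(p_threshold = 0.80))
  expect_true(all(h80$id[h80$passed] %in% h64$id[h64$passed]))
  # AD decisions agree bit-for-bit with the clustering module
  ad <- in_applicability_domain(fx$lib_fps, fx$cm)
  expect_identical(setNames(h64$in_ad, h64$id)[ad$id],
                   setNames(ad$in_ad, ad$id))
})

test_that("docking tables ingest with most-negative-wins deduplication", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tdg_kcal_mol",
               "sonidegib\t-11.0",
               "lapatinib\t-11.8",
               "dup\t-9.0",
               "dup\t-11.8",
               "bad\tnot_a_number"), f)
  dg <- ingest_docking_scores(f)
  expect_equal(unname(dg["sonidegib"]), -11.0)
  expect_equal(unname(dg["dup"]), -11.8)
  rej <- attr(dg, "rejected_lines")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$line, 6L)
  expect_error(ingest_docking_scores("no/such/file.tsv"), "not found")
})

test_that("docking scores integrate into ranking and optional cutoffs", {
  fx <- screen_fixture()
  ids <- fx$lib$records$id
  dock <- setNames(rep(-9.0, length(ids)), ids)
  planted <- names(fx$lib$truth)[fx$lib$truth == "active"]
  dock[planted] <- -11.5
  hits <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                         config = screening_config(dock_dg_cutoff = -11),
                         docking = dock)
  expect_true(all(hits$dock_dg[hits$passed] <= -11))
  expect_warning(
    screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                   docking = setNames(rep(2.5, length(ids)), ids)),
    "positive docking")
})

test_that("reports carry the per-cluster AD breakdown and pass counts", {
  fx <- screen_fixture()
  hits <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm)
  dir <- tempfile("report_")
  paths <- write_screening_report(hits, dir)
  expect_true(all(file.exists(unlist(paths))))
  js <- jsonlite::read_json(paths$json)
  expect_equal(js$n_library, 120L)
  expect_equal(js$n_passed, sum(hits$passed))
  outside <- hits[!hits$in_ad, ]
  expect_equal(sum(unlist(js$outside_ad_by_cluster)), nrow(outside))
  # zero-pass screens still produce a truthful summary
  strict <- screen_library(fx$model, fx$lib_fps, fx$lib_fps, fx$cm,
                           config = screening_config(p_threshold = 0.9999,
                                                     ad_threshold = 0.9999))
  dir2 <- tempfile("report_")
  p2 <- write_screening_report(strict, dir2)
  expect_equal(jsonlite::read_json(p2$json)$n_passed, 0L)
})
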