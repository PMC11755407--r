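test_that("sphere-exclusion clustering recovers planted chemical series", {
  # two coherent, structurally separated series: decorated biphenyl-amides
  # vs decorated morpholine-like aliphatic rings
  heads <- c("", "C", "CC", "CO", "N", "O", "F", "Cl", "Br", "N#C",
             "FC(F)(F)", "CC(C)")
  series_a <- unique(ob_canonical_smiles(
    sprintf("%sc1ccc(-c2ccc(C(=O)NC)cc2)cc1", heads)))
  g <- expand.grid(h = heads, t = c("C", "CC", "O", "OC", "F", "Cl"),
                   stringsAsFactors = FALSE)
  series_b <- unique(ob_canonical_smiles(sprintf("%sC1COC(%s)CN1", g$h, g$t)))
  series_a <- series_a[1:12]; series_b <- series_b[1:25]
  smiles <- c(series_a, series_b)
  fps <- fp_morgan(smiles, ids = sprintf("s%02d", seq_along(smiles)))
  cm <- cluster_dataset(fps, n_target_clusters = 2L, sim_cutoff = 0.25)
  planted <- rep(1:2, c(length(series_a), length(series_b)))
  ari <- mclust::adjustedRandIndex(cm$labels[rownames(fps)], planted)
  expect_gte(ari, 0.9)
  # order independence: permuted input gives the same partition
  perm <- sample(nrow(fps))
  cm2 <- cluster_dataset(fps[perm, ], n_target_clusters = 2L, sim_cutoff = 0.25)
  expect_equal(mclust::adjustedRandIndex(cm$labels[rownames(fps)],
                                         cm2$labels[rownames(fps)]), 1)
})

test_that("degenerate clustering inputs behave", {
  fp <- matrix(rep(c(1L, 0L, 1L, 1L), 10), 10, 4, byrow = TRUE,
               dimnames = list(sprintf("d%02d", 1:10), NULL))
  cm <- cluster_dataset(fp, n_target_clusters = 4L)
  expect_equal(unname(table(cm$labels)[["A"]]), 10L)
  expect_error(cluster_dataset(fp[1:2, ], n_target_clusters = 4L),
               "fewer molecules")
})

test_that("centroid selection maximizes mean similarity with brute force", {
  # construct a hub: b overlaps both a and c, which are disjoint
  fps <- rbind(a = c(1, 1, 1, 1, 0, 0, 0, 0),
               b = c(0, 0, 1, 1, 1, 1, 0, 0),
               c = c(0, 0, 0, 0, 1, 1, 1, 1))
  storage.mode(fps) <- "integer"
  # brute-force oracle
  sims <- tanimoto_matrix(fps); diag(sims) <- 0
  oracle <- rownames(fps)[which.max(rowSums(sims) / 2)]
  expect_equal(find_centroid(fps), oracle)
  expect_equal(oracle, "b")
  # singleton cluster returns its only member
  expect_equal(find_centroid(fps[2, , drop = FALSE]), "b")
  expect_error(find_centroid(fps[0, , drop = FALSE]), "empty")
})

test_that("pruning moves outliers to X and never grows the named clusters", {
  ds <- fx_dataset_clean()
  fps <- fx_fps_clean()
  cm <- cluster_dataset(fps, smiles = setNames(ds$records$smiles, ds$records$id))
  before <- table(factor(cm$labels, levels = c(LETTERS[1:4], "X")))
  pruned <- prune_to_x(cm, fps, threshold = 0.195)
  after <- table(factor(pruned$labels, levels = c(LETTERS[1:4], "X")))
  expect_true(all(after[LETTERS[1:4]] <= before[LETTERS[1:4]]))
  expect_error(prune_to_x(cm, fps, threshold = 1.5), "0,1")
  # an engineered outlier lands in X
  sub <- fps[1:30, ]
  out_fp <- matrix(0L, 1, ncol(fps), dimnames = list("outlier", colnames(fps)))
  out_fp[1, 1000:1010] <- 1L
  cm2 <- cluster_dataset(rbind(sub, out_fp), n_target_clusters = 2L)
  pr2 <- prune_to_x(cm2, rbind(sub, out_fp), threshold = 0.195)
  expect_equal(unname(pr2$labels["outlier"]), "X")
})

test_that("no-op pruning keeps X empty", {
  fp <- matrix(rep(c(1L, 1L, 0L, 1L), 6), 6, 4, byrow = TRUE,
               dimnames = list(sprintf("s%d", 1:6), NULL))
  cm <- cluster_dataset(fp, n_target_clusters = 2L)
  pr <- prune_to_x(cm, fp, threshold = 0.195)
  expect_false("X" %in% pr$labels)
})

test_that("Murcko scaffolds collapse side chains only", {
  sc <- murcko_scaffold(c("Cc1ccccc1", "CCc1ccccc1",
                          "c1ccc(-c2ccccc2)cc1", "CCCC"))
  expect_equal(sc[1], sc[2])         # toluene == ethylbenzene == benzene
  expect_equal(sc[1], "c1ccccc1")
  expect_false(sc[3] == sc[1])       # biphenyl keeps both rings
  expect_equal(sc[4], "")            # acyclic -> empty scaffold
})

test_that("scaffold summaries count distinct frameworks per cluster", {
  smiles <- c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1", "CCCCc1ccccc1",
              "Cc1ccncc1", "CCc1ccncc1", "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",
              "CC1CCCCC1", "CCC1CCCCC1")
  recs <- new_records(sprintf("q%02d", 1:10), smiles, "inactive", "synthetic")
  cm <- structure(list(labels = setNames(rep("A", 10), recs$id),
                       centroids = list(), ad_threshold = 0.195),
                  class = "cluster_model")
  sm <- murcko_summary(recs, cm)
  expect_equal(sm$n_molecules, 10)
  expect_equal(sm$n_scaffolds, 4)    # benzene, pyridine, naphthalene, cyclohexane
  expect_equal(sm$scaffold_pct, 40)
})

test_that("the applicability domain is inclusive at the threshold and monotone", {
  # centroids: two disjoint reference fingerprints
  cent_a <- integer(200); cent_a[1:100] <- 1L
  cent_x <- integer(200); cent_x[151:200] <- 1L
  cm <- structure(list(labels = c(m1 = "A"),
                       centroids = list(A = list(id = "m1", fp = cent_a),
                                        X = list(id = "m2", fp = cent_x)),
                       ad_threshold = 0.195),
                  class = "cluster_model")
  # the centroid itself: similarity 1, cluster A
  res <- in_applicability_domain(matrix(cent_a, 1), cm)
  expect_true(res$in_ad); expect_equal(res$max_similarity, 1)
  expect_equal(res$nearest_cluster, "A")
  # disjoint from every centroid
  far <- integer(200); far[101:120] <- 1L
  res <- in_applicability_domain(matrix(far, 1), cm)
  expect_false(res$in_ad); expect_equal(res$max_similarity, 0)
  # exactly 0.195 = 39/200 shared bits over a union of 200 -> inside
  q <- integer(200); q[1:39] <- 1L; q[101:200] <- 1L  # inter 39, union 200
  expect_equal(suppressWarnings(tanimoto(q, cent_a)), 0.195)
  expect_true(in_applicability_domain(matrix(q, 1), cm)$in_ad)
  # monotonicity: raising the threshold never adds molecules
  set.seed(11)
  probes <- matrix(rbinom(50 * 200, 1, 0.2), 50, 200)
  in_ad <- function(th) {
    cm$ad_threshold <- th
    in_applicability_domain(probes, cm)$in_ad
  }
  prev <- in_ad(0.05)
  for (th in c(0.195, 0.4, 0.7, 0.95)) {
    cur <- in_ad(th)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("cluster models round-trip through JSON", {
  fps <- fx_fps_clean()[1:40, ]
  cm <- cluster_dataset(fps, n_target_clusters = 2L)
  f <- tempfile(fileext = ".json")
  write_cluster_model(cm, f)
  cm2 <- read_cluster_model(f)
  expect_equal(cm2$labels, cm$labels)
  expect_equal(cm2$centroids$A$fp, cm$centroids$A$fp)
  expect_equal(cm2$ad_threshold, cm$ad_threshold)
})
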