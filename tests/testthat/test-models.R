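test_that("confusion metrics match the closed-form definitions", {
  y <- c(rep("active", 3), rep("inactive", 4))
  m <- confusion_metrics(y, y)
  expect_equal(c(m$se, m$sp, m$q, m$mcc), c(1, 1, 1, 1))
  # all-inactive predictions: SE = 0 and the degenerate MCC convention
  m0 <- confusion_metrics(y, rep("inactive", 7))
  expect_equal(m0$se, 0); expect_equal(m0$mcc, 0)
  # direct formula oracle: tp=2 fp=1 tn=3 fn=1 -> (6-1)/sqrt(3*3*4*4) = 5/12
  yt <- c("active", "active", "active", "inactive", "inactive", "inactive", "inactive")
  yp <- c("active", "active", "inactive", "active", "inactive", "inactive", "inactive")
  m1 <- confusion_metrics(yt, yp)
  expect_equal(c(m1$tp, m1$fp, m1$tn, m1$fn), c(2, 1, 3, 1))
  expect_equal(m1$mcc, 5 / 12)
  # MCC is invariant under simultaneous relabelling of both vectors
  sw <- function(v) ifelse(v == "active", "inactive", "active")
  expect_equal(confusion_metrics(sw(yt), sw(yp))$mcc, m1$mcc)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("balanced random forests draw equal class counts per tree", {
  fx <- fx_matrix_rule()
  model <- qsar_train(fx$x, fx$y, family = "rf", n_trees = 100, seed = 3)
  inbag <- model$fit$inbag
  expect_false(is.null(inbag))
  nmin <- min(table(fx$y))
  act <- fx$y == "active"
  per_tree_active <- colSums(inbag[act, , drop = FALSE])
  per_tree_inactive <- colSums(inbag[!act, , drop = FALSE])
  expect_true(all(per_tree_active == nmin))
  expect_true(all(per_tree_inactive == nmin))
})

test_that("random forests are seed-reproducible and learn the planted rule", {
  fx <- fx_matrix_rule()
  m1 <- qsar_train(fx$x, fx$y, family = "rf", n_trees = 200, seed = 5)
  m2 <- qsar_train(fx$x, fx$y, family = "rf", n_trees = 200, seed = 5)
  expect_identical(m1$oob_predictions$p_active, m2$oob_predictions$p_active)
  expect_gte(oob_metrics(m1)$mcc, 0.9)
  # shuffled labels destroy the signal, across five shuffles
  for (s in 1:5) {
    set.seed(100 + s); ysh <- sample(fx$y)
    msh <- qsar_train(fx$x, ysh, family = "rf", n_trees = 150, seed = 5)
    expect_lt(abs(oob_metrics(msh)$mcc), 0.1)
  }
})

test_that("OOB metrics accept alternative cutoffs and reference labels", {
  fx <- fx_matrix_rule()
  m <- qsar_train(fx$x, fx$y, family = "rf", n_trees = 200, seed = 5)
  base <- oob_metrics(m)
  strict <- oob_metrics(m, cutoff = 0.9)
  expect_lte(strict$tp + strict$fp, base$tp + base$fp)
  relabeled <- oob_metrics(m, labels = fx$y)
  expect_equal(relabeled$mcc, base$mcc)
  expect_error(oob_metrics(qsar_train(fx$x, fx$y, family = "svm", C = 1)),
               "random-forest")
})

test_that("permutation importance surfaces the informative bits", {
  fx <- fx_matrix_rule()
  m <- qsar_train(fx$x, fx$y, family = "rf", n_trees = 300, seed = 5)
  rk <- feature_importance(m)
  expect_true(all(diff(rk$importance) <= 1e-12))
  expect_true(all(fx$informative %in% rk$descriptor[1:10]))
  # noise bits score clearly below the informative ones
  noise_mean <- mean(rk$importance[!rk$descriptor %in% fx$informative])
  info_min <- min(rk$importance[rk$descriptor %in% fx$informative])
  expect_gt(info_min, noise_mean)
  # deterministic ranking for a fixed seed
  rk2 <- feature_importance(qsar_train(fx$x, fx$y, family = "rf",
                                       n_trees = 300, seed = 5))
  expect_identical(rk$descriptor, rk2$descriptor)
  # top-k selection
  expect_length(select_top_k(rk, 50), 50L)
  expect_identical(select_top_k(rk, nrow(rk)), rk$descriptor)
  expect_error(select_top_k(rk, 0), "positive")
})

test_that("SVMs separate a separable set and accept stated hyperparameters", {
  fx <- fx_matrix_rule()
  m <- qsar_train(fx$x, fx$y, family = "svm",
                  C = 3.593813663804626, gamma = 0.007742636826811269, seed = 2)
  expect_equal(m$config$C, 3.593813663804626)
  expect_equal(m$config$gamma, 0.007742636826811269)
  expect_gte(mean(predict(m, fx$x, type = "class") == fx$y), 0.97)
  p <- predict(m, fx$x, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("SVM grid search returns an in-range optimum", {
  fx <- fx_matrix_rule()
  tu <- tune_svm(fx$x[1:150, ], fx$y[1:150], C_grid = c(1, 50),
                 gamma_grid = c(1e-4, 1e-2), folds = 3, seed = 4)
  expect_true(tu$C %in% c(1, 50))
  expect_true(tu$gamma %in% c(1e-4, 1e-2))
  expect_equal(nrow(tu$results), 4L)
  expect_true(all(is.finite(tu$results$mcc)))
})

test_that("the MLP learns the planted rule and collapses on constant input", {
  fx <- fx_matrix_mlp()
  m <- qsar_train(fx$x[fx$train, ], fx$y[fx$train], family = "mlp",
                  epochs = 80, seed = 3)
  mt <- confusion_metrics(fx$y[fx$test],
                          predict(m, fx$x[fx$test, ], type = "class"))
  expect_gte(mt$mcc, 0.8)
  # identical seed, identical loss curve
  m2 <- qsar_train(fx$x[fx$train, ], fx$y[fx$train], family = "mlp",
                   epochs = 80, seed = 3)
  expect_identical(m$fit$losses, m2$fit$losses)
  # constant features: predictions collapse to the majority class
  xc <- matrix(1, 120, 8, dimnames = list(NULL, paste0("K", 1:8)))
  yc <- rep(c("active", "inactive"), c(15, 105))
  mc <- qsar_train(xc, yc, family = "mlp", epochs = 30, seed = 1)
  pc <- predict(mc, xc, type = "prob")
  expect_lt(diff(range(pc)), 1e-8)
  expect_true(all(predict(mc, xc, type = "class") == "inactive"))
})

test_that("cross-validation pools stratified out-of-fold predictions", {
  fx <- fx_matrix_rule()
  cv <- cross_validate(fx$x, fx$y, family = "rf", folds = 5, seed = 2,
                       n_trees = 150)
  expect_gte(cv$mcc, 0.9)
  expect_equal(cv$tp + cv$tn + cv$fp + cv$fn, nrow(fx$x))
  set.seed(1); ysh <- sample(fx$y)
  cvs <- cross_validate(fx$x, ysh, family = "rf", folds = 5, seed = 2,
                        n_trees = 150)
  expect_lt(abs(cvs$mcc), 0.15)
  # boundary: 2 folds with 4 molecules per class runs
  xs <- fx$x[1:8, ]; ys <- rep(c("active", "inactive"), 4)
  expect_s3_class(cross_validate(xs, ys, family = "rf", folds = 2, seed = 1,
                                 n_trees = 50),
                  "classification_metrics")
  expect_error(cross_validate(fx$x, fx$y, family = "rf", folds = 1))
})

test_that("random-forest probabilities are exactly the tree vote fractions", {
  fx <- fx_matrix_rule()
  m <- qsar_train(fx$x[1:200, ], fx$y[1:200], family = "rf", n_trees = 100,
                  seed = 8)
  newx <- fx$x[201:220, ]
  p <- predict(m, newx, type = "prob")
  # vote-count oracle: tally individual tree predictions
  votes <- stats::predict(m$fit, newx, predict.all = TRUE)$individual
  frac <- rowMeans(votes == "active")
  expect_equal(p, unname(frac))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(m, newx[, 1:10]), "missing descriptor")
})
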