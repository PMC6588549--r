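test_that("Gini impurity matches its worked values and properties", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(0.7, 0.3)), 0.42)
  expect_error(gini_impurity(c(0.5, 0.4)), "sum to 1")
  expect_error(gini_impurity(c(-0.2, 1.2)), ">= 0")
  set.seed(10)
  for (i in 1:10) {
    f <- as.vector(stats::rmultinom(1, 500, runif(4))) / 500
    # symmetric under label permutation
    expect_equal(gini_impurity(f), gini_impurity(sample(f)))
    # bounded by 1 - 1/C
    expect_lte(gini_impurity(f), 1 - 1 / 4 + 1e-12)
    # concavity: mixing two distributions never lowers impurity below the mix
    g <- as.vector(stats::rmultinom(1, 500, runif(4))) / 500
    expect_gte(gini_impurity((f + g) / 2) + 1e-12,
               (gini_impurity(f) + gini_impurity(g)) / 2)
  }
})

test_that("per-class recall matches a hand-built confusion matrix", {
  expect_equal(per_class_recall(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               c(folded = 1, unfolded = 1))
  expect_equal(per_class_recall(c(0, 0, 1, 1), c(0, 0, 0, 0)),
               c(folded = 1, unfolded = 0))
  set.seed(8)
  for (i in 1:10) {
    truth <- rbinom(50, 1, 0.4)
    pred <- rbinom(50, 1, 0.5)
    cm <- table(factor(truth, 0:1), factor(pred, 0:1))
    expect_equal(unname(per_class_recall(truth, pred)),
                 c(cm[1, 1] / sum(cm[1, ]), cm[2, 2] / sum(cm[2, ])))
  }
  # absent class reports NA; empty test set errors
  expect_true(is.na(per_class_recall(c(1, 1), c(1, 0))[["folded"]]))
  expect_error(per_class_recall(integer(0), integer(0)), "empty")
})

test_that("forests separate a separable toy problem and are deterministic", {
  ds <- make_toy_dataset(seed = 21)
  fo <- a2_forest(ds, n_trees = 40, seed = 3, targets = "chain")
  perf_tr <- performance(fo, ds, split = "train")
  expect_gte(perf_tr$folded_recall, 0.95)
  expect_gte(perf_tr$unfolded_recall, 0.95)
  # deterministic given the seed
  fo2 <- a2_forest(ds, n_trees = 40, seed = 3, targets = "chain")
  expect_identical(predict(fo, ds$features), predict(fo2, ds$features))
  # importances: nonnegative, sum to 1
  imp <- feature_importance(fo)
  v <- imp$raw[["y_chain"]]
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("single-class training targets are rejected with advice", {
  ds <- make_toy_dataset(seed = 5)
  ds$responses[, "y_s2"] <- 0L
  expect_error(a2_forest(ds, n_trees = 10, targets = 2), "single-class")
  ds2 <- make_toy_dataset(seed = 5)
  ds2$split <- NULL
  expect_error(a2_forest(ds2), "split")
})

test_that("duplicating rows of one class does not hurt its training recall", {
  ds <- make_toy_dataset(seed = 31)
  fo <- a2_forest(ds, n_trees = 40, seed = 9, targets = "chain")
  base <- performance(fo, ds, split = "train")$unfolded_recall
  # triple every unfolded-chain training row
  dup <- which(ds$split == "train" & ds$responses[, "y_chain"] == 1L)
  idx <- c(seq_len(nrow(ds$features)), rep(dup, 2))
  ds2 <- ds
  ds2$features <- ds$features[idx, ]
  ds2$responses <- ds$responses[idx, ]
  ds2$provenance <- ds$provenance[idx, ]
  ds2$split <- ds$split[idx]
  fo2 <- a2_forest(ds2, n_trees = 40, seed = 9, targets = "chain")
  boosted <- performance(fo2, ds2, split = "train")$unfolded_recall
  expect_gte(boosted + 1e-9, base)
})

test_that("prediction is majority vote over the fitted ensemble", {
  ds <- make_toy_dataset(seed = 13)
  fo <- a2_forest(ds, n_trees = 25, seed = 2, targets = "chain")
  preds <- predict(fo, ds$features[ds$split == "test", , drop = FALSE])
  expect_true(all(preds %in% 0:1))
  expect_equal(colnames(preds), "y_chain")
  # agreement with ranger's own per-tree majority vote
  rf <- fo$forests[["y_chain"]]
  df <- as.data.frame(ds$features[ds$split == "test", , drop = FALSE],
                      check.names = FALSE)
  all_trees <- stats::predict(rf, df, predict.all = TRUE,
                              num.threads = 1)$predictions
  vote <- as.integer(rowMeans(all_trees == 2) > 0.5)  # class index 2 = "1"
  expect_equal(unname(preds[, 1]), vote)
})
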