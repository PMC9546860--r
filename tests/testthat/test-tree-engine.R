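test_that("gini_impurity and gini_gain match the closed forms", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(8, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)  # 2 * 3/4 * 1/4
  expect_error(gini_impurity(c(0, 0)), "zero")

  expect_equal(gini_gain(c(4, 4), c(4, 0), c(0, 4)), 0.5)
  expect_equal(gini_gain(c(4, 4), c(2, 2), c(2, 2)), 0)
  expect_error(gini_gain(c(4, 4), c(4, 4), c(0, 0)), "non-empty")

  # gain is non-negative for any valid split (concavity)
  set.seed(5)
  for (i in 1:100) {
    parent <- c(sample(1:20, 1), sample(1:20, 1))
    l0 <- sample(0:parent[1], 1); l1 <- sample(0:parent[2], 1)
    left <- c(l0, l1); right <- parent - left
    if (sum(left) == 0 || sum(right) == 0) next
    expect_gte(gini_gain(parent, left, right), -1e-12)
  }
})

test_that("fit_tree handles degenerate label sets and perfect separators", {
  # all-0 labels: fit on a pure subset (the container itself needs both
  # classes, so take the single-class slice through sample_indices)
  d2 <- tiny_data(n = 20, labels = c(rep(0, 19), 1))
  tr <- fit_tree(d2, feature_ref("g1", "a"), sample_indices = 1:19)
  expect_equal(length(tr$feature), 1L)  # single leaf
  expect_equal(tr$prob, 0)
  expect_equal(predict_proba(tr, d2, 1:5), rep(0, 5))

  # one binary feature that separates the classes perfectly: one split
  n <- 30
  samples <- sprintf("s%02d", 1:n)
  X <- matrix(c(rep(0, 15), rep(1, 15)), n, 1,
              dimnames = list(samples, "g1"))
  dd <- multi_omics_data(list(a = X), setNames(c(rep(0, 15), rep(1, 15)),
                                               samples))
  tr2 <- fit_tree(dd, feature_ref("g1", "a"))
  expect_equal(sum(tr2$feature != 0), 1L)
  expect_equal(tr2$threshold[1], 0.5)
  expect_setequal(tr2$prob[tr2$feature == 0], c(0, 1))
  expect_error(fit_tree(dd, feature_ref(character(), character())),
               "non-empty")
})

test_that("a tree on the four XOR features reaches training accuracy 1", {
  # oracle: replay the truth table -- all 16 input combinations occur in the
  # data, so accuracy 1 requires the tree to represent the function exactly
  set.seed(21)
  n <- 1000
  samples <- sprintf("s%04d", 1:n)
  X <- matrix(rbinom(n * 4, 1, 0.5), n,
              dimnames = list(samples, c("f1", "f2", "f3", "f4")))
  y <- as.integer(xor(X[, 1] & X[, 2], X[, 3] & X[, 4]))
  d <- multi_omics_data(list(a = X), setNames(y, samples))
  tr <- fit_tree(d, feature_ref(c("f1", "f2", "f3", "f4"), "a"))
  pred <- as.integer(predict_proba(tr, d) > 0.5)
  expect_equal(mean(pred == y), 1)
  # and the truth table is represented on all 16 combinations
  grid <- as.matrix(expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1, f4 = 0:1))
  rownames(grid) <- sprintf("t%02d", 1:16)
  yg <- as.integer(xor(grid[, 1] & grid[, 2], grid[, 3] & grid[, 4]))
  dg <- multi_omics_data(list(a = grid), setNames(yg, rownames(grid)))
  # predict on the grid through the fitted tree (labels of dg irrelevant)
  pg <- as.integer(predict_proba(tr, dg) > 0.5)
  expect_equal(pg, yg)
})

test_that("split choice agrees with exhaustive search on random instances", {
  set.seed(31)
  for (i in 1:60) {
    p <- sample(2:5, 1)
    n <- sample(8:30, 1)
    continuous <- i %% 2 == 0
    X <- if (continuous) matrix(round(runif(n * p), 2), n)
         else matrix(rbinom(n * p, 1, 0.5), n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    nodes <- sprintf("g%d", 1:p)
    dimnames(X) <- list(sprintf("s%02d", 1:n), nodes)
    d <- multi_omics_data(list(a = X), setNames(y, rownames(X)))
    tr <- fit_tree(d, feature_ref(nodes, "a"))
    oracle <- best_split_brute(X, y)
    if (is.na(oracle$feature)) {
      expect_equal(tr$feature[1], 0L)
    } else {
      expect_equal(tr$feature[1], oracle$feature)
      expect_equal(tr$threshold[1], oracle$threshold)
    }
  }
})

test_that("gain tally sums to the tree's total impurity decrease", {
  set.seed(41)
  for (i in 1:20) {
    rt <- random_small_tree(p = sample(2:6, 1), n = sample(30:80, 1),
                            seed = 100 + i, continuous = i %% 2 == 0)
    expect_equal(sum(rt$tree$gain_tally), tree_impurity_decrease(rt$tree),
                 tolerance = 1e-10)
  }
})

test_that("duplicate feature refs do not change the fitted tree", {
  rt <- random_small_tree(p = 3, n = 50, seed = 77)
  dup <- rbind(rt$tree$features, rt$tree$features[c(2, 1), ])
  tr2 <- fit_tree(rt$data, dup)
  expect_equal(tr2$feature, rt$tree$feature)
  expect_equal(tr2$threshold, rt$tree$threshold)
})

test_that("predict_proba replays in-bag leaf proportions", {
  rt <- random_small_tree(p = 3, n = 60, seed = 5)
  pr <- predict_proba(rt$tree, rt$data)
  leaves <- which(rt$tree$feature == 0L)
  for (lf in leaves) {
    sel <- abs(pr - rt$tree$prob[lf]) < 1e-12
    # every sample landing in this leaf predicts its stored proportion
    expect_true(any(sel) || rt$tree$n[lf] == 0)
  }
  # and the cover-weighted mean equals the base rate
  expect_equal(mean(pr), mean(rt$data$labels), tolerance = 1e-12)
})

test_that("roc_auc equals brute-force pair enumeration", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "gdf_undefined_auc")

  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5
              else runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels), auc_brute(scores, labels))
  }
})

test_that("roc_auc complement identity holds for tie-free scores", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels) + roc_auc(scores, 1 - labels), 1)
  }
})

test_that("bootstrap_sample has ~1/e out-of-bag fraction and is seeded", {
  set.seed(71)
  fr <- replicate(1000, length(bootstrap_sample(1000)$oob) / 1000)
  expect_gt(mean(fr), 0.35)
  expect_lt(mean(fr), 0.39)

  set.seed(8); a <- bootstrap_sample(50)
  set.seed(8); b <- bootstrap_sample(50)
  expect_identical(a, b)
  expect_error(bootstrap_sample(1), "at least 2")

  s <- bootstrap_sample(2)
  expect_true(all(s$oob %in% 1:2))
  expect_length(s$in_bag, 2L)
})

test_that("tree_text dumps every node", {
  rt <- random_small_tree(p = 3, n = 40, seed = 13)
  txt <- tree_text(rt$tree)
  expect_length(txt, length(rt$tree$feature))
  expect_true(any(grepl("leaf", txt)))
})
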