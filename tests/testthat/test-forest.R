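test_that("undersampled bags are class-balanced at the minority count", {
  y <- rep(1:4, c(500, 300, 100, 80))
  bag <- undersample_bag(y, seed = 2)
  expect_length(bag, 4 * 80)
  expect_equal(as.vector(table(y[bag])), rep(80L, 4))

  y2 <- rep(1:2, each = 50)
  bag2 <- undersample_bag(y2, seed = 2)
  expect_length(bag2, 100)
  expect_equal(as.vector(table(y2[bag2])), c(50L, 50L))

  expect_error(undersample_bag(c(1L, 1L, 3L)), "zero records")
})

test_that("within-class bootstrap has the 1 - 1/e unique fraction", {
  y <- rep(1:2, each = 1000)
  bag <- undersample_bag(y, seed = 7)
  cls1 <- bag[y[bag] == 1]
  expect_equal(length(unique(cls1)) / 1000, 1 - exp(-1), tolerance = 0.08)
})

test_that("best_split handles forced and degenerate cases", {
  # pure node: nothing to gain
  expect_null(best_split(c(1, 2, 3, 4), c(1L, 1L, 1L, 1L)))
  # constant predictor
  expect_null(best_split(rep(2, 6), rep(1:2, 3)))
  # perfect separation: midpoint threshold, both children pure
  s <- best_split(c(1, 2, 3, 10, 11, 12), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(s$threshold, 6.5)
  expect_equal(s$gain, 0.5)  # parent Gini 0.5, children pure
})

test_that("best_split matches the exhaustive Gini oracle on random nodes", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    x <- round(stats::runif(n, 0, 10), sample(c(0, 1, 2), 1))
    y <- sample.int(k, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    min_child <- sample(1:3, 1)
    got <- best_split(x, y, min_child = min_child)
    want <- oracle_split_cont(x, y, k, min_child = min_child)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-10)
    }
  }
})

test_that("categorical best_split matches the exhaustive partition oracle", {
  set.seed(456)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    L <- sample(3:7, 1)
    x <- factor(sample(letters[1:L], n, replace = TRUE),
                levels = letters[1:7])
    y <- sample.int(k, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- best_split(x, y)
    want <- oracle_split_cat(x, y, k)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gain, want$gain, tolerance = 1e-10)
      expect_setequal(got$left_levels, want$left_levels)
    }
  }
})

test_that("tree growing respects stopping rules and purity", {
  X <- data.frame(x = c(1, 2, 3, 10, 11, 12))
  y <- c(1L, 1L, 1L, 2L, 2L, 2L)

  # nodesize >= bag size: a single leaf voting the bag frequencies
  tr <- grow_tree(X, y, mtry = 1, nodesize = 6)
  expect_equal(tr$var, 0L)
  expect_equal(tr$votes[1, ], c(0.5, 0.5))

  # one perfectly separating predictor: depth-1 tree, two pure leaves
  tr2 <- grow_tree(X, y, mtry = 1, nodesize = 1)
  expect_equal(tr2$var[1], 1L)
  expect_equal(tr2$thr[1], 6.5)
  expect_equal(sort(tr2$votes[2:3, 1]), c(0, 1))
  expect_length(tr2$var, 3)

  # terminal nodes never fall below nodesize
  set.seed(9)
  Xr <- data.frame(a = stats::runif(200), b = stats::runif(200))
  yr <- sample.int(3, 200, replace = TRUE)
  tr3 <- grow_tree(Xr, yr, mtry = 2, nodesize = 20)
  expect_true(all(tr3$n[tr3$var == 0L] >= 20))
})

test_that("forests are deterministic given the seed", {
  ds <- separable_ds()
  p <- forest_params(ntree = 20, mtry = 1, nodesize = 50, seed = 4)
  f1 <- train_forest(ds, p)
  f2 <- train_forest(ds, p)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
})

test_that("a separable 4-group dataset is learned almost perfectly", {
  ds <- separable_ds()
  f <- train_forest(ds, forest_params(ntree = 500, mtry = 1, nodesize = 20,
                                      seed = 8))
  m <- macroranges:::oob_metrics(f, ds)
  expect_gte(m$accuracy, 0.9)
  expect_gte(m$kappa, 0.85)
})

test_that("label permutation drives OOB kappa to zero", {
  ds <- default_ds()
  set.seed(33)
  ds_perm <- make_ds(ds$X, sample(ds$y))
  f <- train_forest(ds_perm, forest_params(ntree = 300, mtry = 1,
                                           nodesize = 200, seed = 5))
  m <- macroranges:::oob_metrics(f, ds_perm)
  expect_lt(abs(m$kappa), 0.05)
})

test_that("voting fractions are normalized and tie-broken consistently", {
  f <- default_forest()
  ds <- default_split()$train
  votes <- predict_votes(f, ds$X[1:50, ])
  expect_equal(rowSums(votes), rep(1, 50))
  expect_equal(attr(votes, "pred"),
               apply(votes, 1, function(v) which.max(v)),
               ignore_attr = TRUE)

  # single-tree forest returns that tree's leaf distribution
  f1 <- structure(c(f["params"], list(trees = f$trees[1], bags = f$bags[1],
                                      schema = f$schema,
                                      classes = f$classes,
                                      n_records = f$n_records)),
                  class = "rf_forest")
  v1 <- predict_votes(f1, ds$X[1:10, ])
  expect_true(all(v1 %in% f$trees[[1]]$votes))
})

test_that("single-leaf trees vote the undersampled (uniform) priors", {
  ds <- default_ds()
  f <- train_forest(ds, forest_params(ntree = 50, mtry = 1,
                                      nodesize = 10000, seed = 5))
  votes <- predict_votes(f, ds$X[1:5, ])
  expect_equal(unname(votes[1, ]), rep(0.25, 4), tolerance = 1e-10)
})

test_that("OOB bookkeeping: coverage, and OOB <= in-bag accuracy", {
  ds <- separable_ds()
  p1 <- forest_params(ntree = 1, mtry = 2, nodesize = 30, seed = 6)
  f1 <- train_forest(ds, p1)
  oob <- oob_predict(f1, ds)
  inbag <- unique(f1$bags[[1]])
  expect_setequal(which(oob$covered), setdiff(seq_along(ds$y), inbag))

  f <- train_forest(ds, forest_params(ntree = 300, mtry = 1, nodesize = 20,
                                      seed = 6))
  oob300 <- oob_predict(f, ds)
  expect_true(all(oob300$covered))  # every record OOB for some tree
  m_oob <- macroranges:::oob_metrics(f, ds)
  votes_in <- predict_votes(f, ds)
  m_in <- accuracy(confusion(ds$y, attr(votes_in, "pred"), ds$k))
  expect_lte(m_oob$accuracy, m_in + 1e-9)
})

test_that("OOB kappa has converged by desk-scale ntree", {
  ds <- default_ds()
  k1 <- macroranges:::oob_metrics(
    train_forest(ds, forest_params(ntree = 2000, mtry = 1, nodesize = 200,
                                   seed = 12)), ds)$kappa
  k2 <- macroranges:::oob_metrics(
    train_forest(ds, forest_params(ntree = 4000, mtry = 1, nodesize = 200,
                                   seed = 13)), ds)$kappa
  expect_lt(abs(k1 - k2), 0.02)
})

test_that("OOB metrics agree with the reference forest implementation", {
  ds <- default_ds()
  f <- train_forest(ds, forest_params(ntree = 1000, mtry = 1,
                                      nodesize = 200, seed = 3))
  ours <- macroranges:::oob_metrics(f, ds)
  y <- factor(ds$y)
  set.seed(3)
  ref <- randomForest::randomForest(
    ds$X, y, ntree = 1000, mtry = 1, nodesize = 200, strata = y,
    sampsize = rep(min(table(y)), ds$k), replace = TRUE)
  cm <- confusion(ds$y, as.integer(ref$predicted))
  expect_lt(abs(ours$accuracy - accuracy(cm)), 0.05)
  expect_lt(abs(ours$kappa - cohens_kappa(cm)), 0.05)
})

test_that("missing predictors are rejected at prediction time", {
  f <- default_forest()
  X <- default_split()$train$X[1:3, ]
  X$depth[2] <- NA
  expect_error(predict_votes(f, X), "missing")
})
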