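test_that("root split points are read off the root nodes only", {
  # hand-built 3-tree forest: roots x<=2, y<=9, x<=4
  f <- stub_forest(list(stub_split_tree(1, 2), stub_split_tree(2, 9),
                        stub_split_tree(1, 4)),
                   names = c("x", "y"))
  rs <- root_split_points(f)
  expect_equal(rs$thresholds$x, c(2, 4))
  expect_equal(rs$thresholds$y, 9)
  expect_equal(rs$no_split_count, 0L)

  # leaf-rooted trees are tallied separately
  f2 <- stub_forest(list(stub_leaf_tree(c(1, 0)), stub_split_tree(1, 5)),
                    names = c("x", "y"))
  rs2 <- root_split_points(f2)
  expect_equal(rs2$no_split_count, 1L)
  expect_equal(rs2$thresholds$x, 5)
})

test_that("discriminative ranges summarize the threshold spread", {
  f <- stub_forest(list(stub_split_tree(1, 2), stub_split_tree(1, 4),
                        stub_split_tree(1, 9)),
                   names = c("x", "y"))
  r <- discriminative_ranges(f)
  rx <- r[r$variable == "x", ]
  expect_equal(c(rx$min, rx$mean, rx$max), c(2, 5, 9))
  expect_equal(rx$count, 3L)
  ry <- r[r$variable == "y", ]
  expect_equal(ry$count, 0L)
  expect_true(is.na(ry$mean))

  f3 <- stub_forest(rep(list(stub_split_tree(1, 5)), 4), names = c("x"))
  r3 <- discriminative_ranges(f3)
  expect_equal(c(r3$min, r3$mean, r3$max), c(5, 5, 5))
})

test_that("with mtry = 1 every predictor roots a binomial share of trees", {
  f <- default_forest()
  r <- discriminative_ranges(f)
  counts <- c(r$count, attr(r, "categorical_counts"))
  expect_length(counts, 7)
  expect_equal(sum(counts) + attr(r, "no_split_count"), 300)
  expect_equal(attr(r, "no_split_count"), 0L)
  gof <- stats::chisq.test(counts, p = rep(1 / 7, 7))
  expect_gt(gof$p.value, 0.01)
  # root thresholds stay inside the observed range of their variable
  th <- attr(r, "thresholds")
  X <- default_split()$train$X
  for (v in names(th)) {
    if (length(th[[v]]) == 0) next
    expect_true(all(th[[v]] > min(X[[v]]) & th[[v]] < max(X[[v]])))
  }
})

test_that("a planted phosphorus step threshold is recovered by the ranges", {
  sf <- step_bundle_forest(seed = 101)
  r <- discriminative_ranges(sf$forest)
  tp <- r[r$variable == "total_phosphorus", ]
  expect_gt(tp$count, 0)
  expect_lte(tp$min, 130)
  expect_gte(tp$max, 130)
  expect_lt(abs(tp$mean - 130) / 130, 0.2)
})

test_that("partial dependence equals the brute-force substitution oracle", {
  ds_full <- default_ds()
  ds <- make_ds(ds_full$X[1:50, ], ds_full$y[1:50])
  f <- default_forest()
  grid <- stats::quantile(ds$X$depth, c(0.1, 0.5, 0.9), names = FALSE)
  pdp <- partial_dependence(f, ds, "depth", grid = grid)
  for (i in seq_along(grid)) {
    per_row <- vapply(seq_len(50), function(r) {
      X <- ds$X[r, , drop = FALSE]
      X$depth <- grid[i]
      predict_votes(f, X)[1, ]
    }, numeric(4))
    expect_equal(unname(unlist(pdp[i, -1])), rowMeans(per_row),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(rowSums(pdp[, -1]), rep(1, nrow(pdp)), ignore_attr = TRUE)
})

test_that("pdp grid defaults stay inside the observed 1-99% range", {
  f <- default_forest()
  ds <- default_ds()
  pdp <- partial_dependence(f, ds, "width")
  expect_lte(nrow(pdp), 25)
  expect_true(all(diff(pdp$grid) > 0))
  expect_gte(min(pdp$grid), stats::quantile(ds$X$width, 0.01) - 1e-9)
  expect_lte(max(pdp$grid), stats::quantile(ds$X$width, 0.99) + 1e-9)
  expect_error(partial_dependence(f, ds, "width", grid = numeric(0)),
               "empty grid")
  expect_error(partial_dependence(f, ds, "substrate"))
})

test_that("a model that ignores the variable yields a flat pdp", {
  f <- stub_forest(list(stub_leaf_tree(c(0.3, 0.7))), names = c("x", "y"))
  ds <- make_ds(data.frame(x = stats::runif(20), y = stats::runif(20)),
                rep(1:2, 10))
  pdp <- partial_dependence(f, ds, "x", grid = c(0.1, 0.5, 0.9))
  expect_equal(pdp$group1, rep(0.3, 3))
  expect_equal(pdp$group2, rep(0.7, 3))
})

test_that("below-threshold niches give non-increasing pdp curves", {
  sf <- step_bundle_forest(seed = 101)
  pdp <- partial_dependence(sf$forest, sf$ds, "total_phosphorus")
  g1 <- pdp$group1  # the below-threshold group's voting fraction
  smooth <- stats::filter(g1, rep(1 / 3, 3), sides = 2)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) <= 0.01))
  expect_lt(g1[length(g1)], g1[1])
})

test_that("substrate categories map to their most likely group", {
  # stub that always votes group 2
  f <- stub_forest(list(stub_leaf_tree(c(0, 1, 0))),
                   names = c("width", "substrate"),
                   is_cat = c(FALSE, TRUE),
                   levels = list(NULL, substrate_levels()), k = 3)
  ds <- make_ds(data.frame(width = c(2, 5),
                           substrate = factor(c("Sand", "Gravel"),
                                              levels = substrate_levels())),
                c(1L, 1L, 2L, 3L)[c(1, 4)])
  out <- substrate_top_group(f, ds)
  expect_equal(nrow(out), 7)
  expect_true(all(out$top_group == 2))
  expect_equal(out$category, substrate_levels())

  # planted preference: the separable rule assigns coarse substrate to the
  # higher group index at fixed phosphorus
  ds_sep <- separable_ds()
  f_sep <- train_forest(ds_sep, forest_params(ntree = 300, mtry = 1,
                                              nodesize = 20, seed = 8))
  tab <- substrate_top_group(f_sep, ds_sep)
  expect_true(tab$top_group[tab$category == "Rock and gravel"] %in% c(2, 4))
  expect_true(tab$top_group[tab$category == "Silt and sand"] %in% c(1, 3))
})

test_that("the range overlay report pairs every variable once", {
  f <- default_forest()
  ds <- default_split()$train
  r <- discriminative_ranges(f)
  pdps <- lapply(stats::setNames(nm = r$variable), function(v)
    partial_dependence(f, ds, v, n_grid = 5))
  rep_ <- range_overlay_report(r, pdps)
  expect_setequal(names(rep_), env_variables())
  for (v in names(rep_)) {
    expect_equal(rep_[[v]]$min, r$min[r$variable == v])
    expect_equal(rep_[[v]]$mean, r$mean[r$variable == v])
  }
  expect_error(range_overlay_report(r, pdps[-1]), "match")
})
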