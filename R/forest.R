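# Classification (and internal regression) forest with per-tree class
# undersampling, a configurable number of candidate predictors per node
# (mtry), minimum terminal node size, out-of-bag prediction and full node
# introspection.  Node introspection is the point: the discriminative-range
# statistic reads split thresholds straight off the root nodes, so trees
# are stored as flat, inspectable arrays rather than an opaque handle.
#
# Conventions (fixed, relied on by the ranges module):
#   * continuous splits test "x <= threshold goes left"; thresholds sit at
#     midpoints of consecutive distinct sorted values;
#   * categorical splits send a bitmask-encoded subset of levels left;
#   * split criterion is Gini impurity decrease (entropy via `criterion`);
#   * ties in gain break to the lower variable index, then the lower
#     threshold / subset mask, making trees deterministic given the RNG.

#' Forest hyper-parameters
#'
#' @param ntree Number of trees (published configuration: 7000; desk-scale
#'   default 500).
#' @param mtry Number of candidate predictors drawn (without replacement)
#'   at each node; 1 in the published configuration, which makes every
#'   predictor equally likely to occupy the root node.
#' @param nodesize Minimum number of bag records in a terminal node; a
#'   node is split only if both children would hold at least `nodesize`
#'   records (published configuration: 200).
#' @param seed Integer seed for the bagging/tree RNG stream.
#' @param replace Sample within each class stratum with replacement
#'   (bootstrap, the default) or without.
#' @param criterion Split criterion, `"gini"` (default) or `"entropy"`.
#' @return A `forest_params` list.
#' @export
forest_params <- function(ntree = 500, mtry = 1, nodesize = 200, seed = 1,
                          replace = TRUE, criterion = c("gini", "entropy")) {
  criterion <- match.arg(criterion)
  stopifnot(ntree >= 1, mtry >= 1, nodesize >= 1)
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 nodesize = as.integer(nodesize), seed = as.integer(seed),
                 replace = replace, criterion = criterion),
            class = "forest_params")
}

# ---- internal column representation ---------------------------------------

# Convert a predictor data frame to parallel column vectors: numeric for
# continuous predictors, integer level codes for factors.
.fx_build <- function(X, levels_ref = NULL) {
  p <- ncol(X)
  cols <- vector("list", p)
  is_cat <- logical(p)
  levels_ <- vector("list", p)
  for (j in seq_len(p)) {
    v <- X[[j]]
    if (is.factor(v) || is.character(v)) {
      lv <- if (!is.null(levels_ref)) levels_ref[[j]] else
        if (is.factor(v)) levels(v) else sort(unique(v))
      f <- factor(v, levels = lv)
      if (anyNA(f) && !anyNA(v))
        stop("predictor '", names(X)[j], "' has level(s) unseen in training")
      cols[[j]] <- as.integer(f)
      is_cat[j] <- TRUE
      levels_[[j]] <- lv
    } else {
      cols[[j]] <- as.numeric(v)
    }
  }
  if (anyNA(unlist(cols, use.names = FALSE)))
    stop("predictors contain missing values; impute first")
  list(cols = cols, is_cat = is_cat, levels = levels_, names = names(X),
       p = p, n = nrow(X))
}

# ---- split search ---------------------------------------------------------

# Per-side purity score.  Maximising sum over children of score(child)/n
# is equivalent to minimising the weighted impurity for both criteria.
.score_counts <- function(sumsq, n, criterion) {
  if (criterion == "gini") sumsq / n else sumsq  # entropy handled separately
}

# Best split of a continuous predictor.  x, y restricted to the node's bag
# rows (duplicates allowed).  Returns NULL or list(threshold, gain).
.split_cont <- function(x, y, k, min_child, criterion = "gini",
                        reg = FALSE) {
  n <- length(x)
  if (n < 2 * min_child) return(NULL)
  o <- order(x)
  xs <- x[o]
  nl <- seq_len(n - 1)
  valid <- xs[nl] < xs[nl + 1]
  valid <- valid & nl >= min_child & (n - nl) >= min_child
  if (!any(valid)) return(NULL)
  nr <- n - nl
  if (reg) {
    ys <- y[o]
    cs <- cumsum(ys)
    tot <- cs[n]
    crit <- cs[nl]^2 / nl + (tot - cs[nl])^2 / nr
    parent <- tot^2 / n
  } else {
    ys <- y[o]
    cc <- vapply(seq_len(k), function(cl) cumsum(ys == cl), numeric(n))
    tot <- cc[n, ]
    ccl <- cc[nl, , drop = FALSE]
    ccr <- matrix(tot, n - 1, k, byrow = TRUE) - ccl
    if (criterion == "gini") {
      crit <- rowSums(ccl^2) / nl + rowSums(ccr^2) / nr
      parent <- sum(tot^2) / n
    } else {
      ent <- function(cnt, m) {
        pr <- cnt / m
        rowSums(ifelse(pr > 0, pr * log(pr), 0)) * m
      }
      crit <- ent(ccl, nl) + ent(ccr, nr)
      pt <- tot / n
      parent <- sum(ifelse(pt > 0, pt * log(pt), 0)) * n
    }
  }
  crit[!valid] <- -Inf
  i <- which.max(crit)
  gain <- (crit[i] - parent) / n
  if (!is.finite(gain) || gain <= 1e-12) return(NULL)
  list(threshold = (xs[i] + xs[i + 1]) / 2, gain = gain)
}

# Best binary partition of observed levels of a categorical predictor.
# Returns NULL or list(mask, gain); mask is a bit mask over the FULL level
# set (bit l-1 set => level l goes left).
.split_cat <- function(code, y, k, min_child, criterion = "gini",
                       reg = FALSE) {
  n <- length(code)
  if (n < 2 * min_child) return(NULL)
  present <- sort(unique(code))
  L <- length(present)
  if (L < 2) return(NULL)
  if (reg) {
    sums <- vapply(present, function(l) sum(y[code == l]), 0)
    cnts <- vapply(present, function(l) sum(code == l), 0)
    tot <- sum(sums)
    parent <- tot^2 / n
  } else {
    cnt <- t(vapply(present, function(l) tabulate(y[code == l], k),
                    integer(k)))  # L x k
    cnts <- rowSums(cnt)
    tot <- colSums(cnt)
    if (criterion == "gini") {
      parent <- sum(tot^2) / n
    } else {
      pt <- tot / n
      parent <- sum(ifelse(pt > 0, pt * log(pt), 0)) * n
    }
  }
  best_gain <- 1e-12
  best_mask <- NULL
  # level present[L] is pinned to the right side to halve the enumeration
  for (m in seq_len(2^(L - 1) - 1)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(L - 1) - 1)))
    sel <- c(sel, FALSE)
    n_l <- sum(cnts[sel])
    n_r <- n - n_l
    if (n_l < min_child || n_r < min_child) next
    if (reg) {
      s_l <- sum(sums[sel])
      crit <- s_l^2 / n_l + (tot - s_l)^2 / n_r
    } else {
      c_l <- colSums(cnt[sel, , drop = FALSE])
      c_r <- tot - c_l
      if (criterion == "gini") {
        crit <- sum(c_l^2) / n_l + sum(c_r^2) / n_r
      } else {
        e <- function(cc, m0) {
          pr <- cc / m0
          sum(ifelse(pr > 0, pr * log(pr), 0)) * m0
        }
        crit <- e(c_l, n_l) + e(c_r, n_r)
      }
    }
    gain <- (crit - parent) / n
    if (gain > best_gain) {
      best_gain <- gain
      best_mask <- sum(2^(present[sel] - 1))
    }
  }
  if (is.null(best_mask)) return(NULL)
  list(mask = as.integer(best_mask), gain = best_gain)
}

#' Best single-variable split of a node
#'
#' Exhaustively evaluates the candidate splits of one predictor at a node:
#' for a continuous predictor, every midpoint between consecutive distinct
#' sorted values; for a factor, every binary partition of its observed
#' levels.  The split maximising the impurity decrease (Gini by default)
#' is returned, or `NULL` when no split reduces impurity or respects
#' `min_child`.
#'
#' @param x Predictor values at the node (numeric, or factor for a
#'   categorical predictor).
#' @param y Integer class labels in `1..k` (or numeric response with
#'   `type = "regression"`, where the criterion is variance reduction).
#' @param min_child Minimum number of records each child must hold.
#' @param type `"classification"` or `"regression"`.
#' @param criterion `"gini"` or `"entropy"` (classification only).
#' @return `NULL`, or a list with `gain` and either `threshold` (numeric
#'   `x`; rule is `x <= threshold` goes left) or `left_levels` (factor
#'   `x`; levels sent left).
#' @export
best_split <- function(x, y, min_child = 1,
                       type = c("classification", "regression"),
                       criterion = c("gini", "entropy")) {
  type <- match.arg(type)
  criterion <- match.arg(criterion)
  reg <- type == "regression"
  if (is.factor(x)) {
    s <- .split_cat(as.integer(x), if (reg) y else as.integer(y),
                    k = if (reg) 0L else max(y), min_child, criterion, reg)
    if (is.null(s)) return(NULL)
    lv <- levels(x)
    list(left_levels = lv[bitwAnd(s$mask, 2^(seq_along(lv) - 1)) > 0],
         gain = s$gain)
  } else {
    .split_cont(as.numeric(x), if (reg) y else as.integer(y),
                k = if (reg) 0L else max(y), min_child, criterion, reg)
  }
}

# ---- tree growing ---------------------------------------------------------

# Recursive CART on bag rows (with multiplicity).  Returns a flat tree:
# var (0 = leaf), thr, cmask, left, right, n, and leaf votes (class
# frequencies) or leaf value (mean response).
.grow_tree <- function(fx, rows, y, k, mtry, nodesize, criterion = "gini",
                       reg = FALSE) {
  cap <- 64L
  var <- integer(cap); thr <- numeric(cap); cmask <- integer(cap)
  left <- integer(cap); right <- integer(cap); nn_rec <- integer(cap)
  votes <- if (!reg) matrix(0, cap, k)
  value <- if (reg) numeric(cap)
  n_nodes <- 0L
  ensure <- function() {
    if (n_nodes <= cap) return()
    cap2 <- cap * 2L
    length(var) <<- cap2; length(thr) <<- cap2; length(cmask) <<- cap2
    length(left) <<- cap2; length(right) <<- cap2; length(nn_rec) <<- cap2
    if (!reg) {
      v2 <- matrix(0, cap2, k); v2[seq_len(cap), ] <- votes; votes <<- v2
    } else length(value) <<- cap2
    cap <<- cap2
  }
  mtry_eff <- min(mtry, fx$p)
  recurse <- function(rows) {
    n_nodes <<- n_nodes + 1L
    ensure()
    id <- n_nodes
    yv <- y[rows]
    nn_rec[id] <<- length(rows)
    as_leaf <- function() {
      var[id] <<- 0L
      if (reg) value[id] <<- mean(yv)
      else votes[id, ] <<- tabulate(yv, k) / length(yv)
      id
    }
    pure <- if (reg) stats::var(yv) == 0 || length(yv) == 1 else
      all(yv == yv[1])
    if (length(rows) < 2L * nodesize || pure) return(as_leaf())
    cands <- sort(sample.int(fx$p, mtry_eff))
    best <- NULL; best_v <- 0L
    for (v in cands) {
      xv <- fx$cols[[v]][rows]
      s <- if (fx$is_cat[v])
        .split_cat(xv, yv, k, nodesize, criterion, reg)
      else
        .split_cont(xv, yv, k, nodesize, criterion, reg)
      if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
        best <- s; best_v <- v
      }
    }
    if (is.null(best)) return(as_leaf())
    var[id] <<- best_v
    xv <- fx$cols[[best_v]][rows]
    if (fx$is_cat[best_v]) {
      cmask[id] <<- best$mask
      go_left <- bitwAnd(bitwShiftL(1L, xv - 1L), best$mask) > 0L
    } else {
      thr[id] <<- best$threshold
      go_left <- xv <= best$threshold
    }
    l <- recurse(rows[go_left])
    r <- recurse(rows[!go_left])
    left[id] <<- l
    right[id] <<- r
    id
  }
  recurse(rows)
  idx <- seq_len(n_nodes)
  out <- list(var = var[idx], thr = thr[idx], cmask = cmask[idx],
              left = left[idx], right = right[idx], n = nn_rec[idx])
  if (reg) out$value <- value[idx] else
    out$votes <- votes[idx, , drop = FALSE]
  structure(out, class = "rf_tree")
}

#' Grow a single decision tree
#'
#' Recursive partitioning on the supplied rows: at each node `mtry`
#' candidate predictors are drawn uniformly without replacement and the
#' best split among them is taken; a node becomes a leaf when it is pure,
#' holds fewer than `2 * nodesize` records, or no candidate split improves
#' impurity with both children at least `nodesize`.  Leaves store the
#' class frequencies of the bag records they hold.
#'
#' @param X Data frame of complete predictors.
#' @param y Integer class labels in `1..k`.
#' @param mtry,nodesize,criterion See [forest_params()].
#' @param rows Bag record indices (with multiplicity); default all rows.
#' @param k Number of classes (default `max(y)`).
#' @return An `rf_tree`: flat arrays `var` (0 = leaf), `thr`, `cmask`,
#'   `left`, `right`, `n` and leaf `votes`.
#' @export
grow_tree <- function(X, y, mtry = 1, nodesize = 1, criterion = "gini",
                      rows = seq_along(y), k = max(y)) {
  fx <- .fx_build(X)
  .grow_tree(fx, rows, as.integer(y), as.integer(k), mtry, nodesize,
             criterion)
}

# Route rows through a tree; returns the leaf node id per row.
.route_tree <- function(tree, cols, is_cat, rows) {
  out <- integer(length(rows))
  rec <- function(node, pos) {
    v <- tree$var[node]
    if (v == 0L) {
      out[pos] <<- node
      return()
    }
    x <- cols[[v]][rows[pos]]
    go_left <- if (is_cat[v])
      bitwAnd(bitwShiftL(1L, x - 1L), tree$cmask[node]) > 0L
    else x <= tree$thr[node]
    if (any(go_left)) rec(tree$left[node], pos[go_left])
    if (!all(go_left)) rec(tree$right[node], pos[!go_left])
  }
  if (length(rows) > 0) rec(1L, seq_along(rows))
  out
}

# ---- bagging --------------------------------------------------------------

#' Class-balanced undersampled bag
#'
#' Draws `m` records per class, where `m` is the minority class count, so
#' every tree sees an equal number of records from each group; sampling is
#' within-class, with replacement by default (bootstrap).
#'
#' @param labels Integer class labels in `1..k`.
#' @param seed Optional integer seed (omit inside a seeded stream).
#' @param replace Sample with replacement within each class (default).
#' @return Integer vector of record indices, `m` per class.
#' @export
undersample_bag <- function(labels, seed = NULL, replace = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  k <- max(labels)
  counts <- tabulate(labels, k)
  if (any(counts == 0))
    stop("class(es) with zero records: ",
         paste(which(counts == 0), collapse = ", "))
  m <- min(counts)
  unlist(lapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx), m, replace = replace)]
  }), use.names = FALSE)
}

# ---- forest ---------------------------------------------------------------

#' Train a class-undersampled classification forest
#'
#' `ntree` independent (bag, tree) pairs from a single seeded RNG stream.
#' Each bag is a class-balanced undersample ([undersample_bag()]); bags are
#' retained per tree for out-of-bag prediction, and trees are stored in an
#' inspectable flat form so root-node split thresholds can be read off
#' directly ([root_split_points()]).
#'
#' @param ds A `model_dataset` (complete predictors).
#' @param params A [forest_params()].
#' @return An `rf_forest`: `trees`, `bags`, `params`, `schema`, `classes`,
#'   `n_records`.
#' @export
train_forest <- function(ds, params = forest_params()) {
  stopifnot(inherits(ds, "model_dataset"))
  fx <- .fx_build(ds$X)
  y <- as.integer(ds$y)
  k <- ds$k
  if (any(tabulate(y, k) == 0))
    stop("class(es) absent from dataset")
  set.seed(params$seed)
  trees <- vector("list", params$ntree)
  bags <- vector("list", params$ntree)
  for (t in seq_len(params$ntree)) {
    bag <- undersample_bag(y, replace = params$replace)
    trees[[t]] <- .grow_tree(fx, bag, y, k, params$mtry, params$nodesize,
                             params$criterion)
    bags[[t]] <- bag
  }
  structure(list(trees = trees, bags = bags, params = params,
                 schema = list(names = fx$names, is_cat = fx$is_cat,
                               levels = fx$levels),
                 classes = seq_len(k), n_records = fx$n),
            class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat("rf_forest:", length(x$trees), "trees,", length(x$classes),
      "classes, mtry =", x$params$mtry, ", nodesize =",
      x$params$nodesize, "\n")
  invisible(x)
}

# Build prediction columns from new data against the training schema.
.fx_newdata <- function(forest, newdata) {
  if (inherits(newdata, "model_dataset")) newdata <- newdata$X
  newdata <- as.data.frame(newdata)[, forest$schema$names, drop = FALSE]
  .fx_build(newdata, levels_ref = forest$schema$levels)
}

#' Per-class voting fractions
#'
#' Soft vote: the average of leaf class-frequency distributions across all
#' trees.  Fractions sum to 1 per record; the predicted class is the
#' argmax, ties resolved to the lowest label index.
#'
#' @param forest An `rf_forest`.
#' @param newdata Data frame of complete predictors (or `model_dataset`).
#' @return Matrix n x k of voting fractions, attribute `"pred"` holding
#'   predicted labels.
#' @export
predict_votes <- function(forest, newdata) {
  fx <- .fx_newdata(forest, newdata)
  n <- fx$n
  k <- length(forest$classes)
  acc <- matrix(0, n, k)
  rows <- seq_len(n)
  for (tree in forest$trees) {
    leaf <- .route_tree(tree, fx$cols, forest$schema$is_cat, rows)
    acc <- acc + tree$votes[leaf, , drop = FALSE]
  }
  votes <- acc / length(forest$trees)
  colnames(votes) <- paste0("group", forest$classes)
  attr(votes, "pred") <- max.col(votes, ties.method = "first")
  votes
}

#' Out-of-bag voting fractions and predictions
#'
#' For each training record, averages leaf distributions over the trees
#' whose bag excludes it.  Records that are in-bag for every tree are
#' flagged uncovered and excluded from metrics.
#'
#' @param forest An `rf_forest` trained on `ds`.
#' @param ds The `model_dataset` the forest was trained on.
#' @return List with `votes` (n x k), `pred` (NA where uncovered),
#'   `n_trees_oob` and `covered`.
#' @export
oob_predict <- function(forest, ds) {
  fx <- .fx_build(ds$X)
  if (fx$n != forest$n_records)
    stop("dataset does not match the forest's training data")
  k <- length(forest$classes)
  acc <- matrix(0, fx$n, k)
  cnt <- integer(fx$n)
  for (t in seq_along(forest$trees)) {
    inbag <- tabulate(forest$bags[[t]], fx$n) > 0L
    oob <- which(!inbag)
    if (length(oob) == 0) next
    leaf <- .route_tree(forest$trees[[t]], fx$cols, forest$schema$is_cat,
                        oob)
    acc[oob, ] <- acc[oob, ] + forest$trees[[t]]$votes[leaf, , drop = FALSE]
    cnt[oob] <- cnt[oob] + 1L
  }
  covered <- cnt > 0L
  votes <- acc
  votes[covered, ] <- votes[covered, ] / cnt[covered]
  colnames(votes) <- paste0("group", forest$classes)
  pred <- rep(NA_integer_, fx$n)
  pred[covered] <- max.col(votes[covered, , drop = FALSE],
                           ties.method = "first")
  list(votes = votes, pred = pred, n_trees_oob = cnt, covered = covered)
}

# ---- internal regression forest (used by the iterative imputer) ------------

# Plain bootstrap regression forest with mean leaves.
.train_forest_reg <- function(X, yv, ntree, mtry, nodesize) {
  fx <- .fx_build(X)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    bag <- sample.int(fx$n, fx$n, replace = TRUE)
    trees[[t]] <- .grow_tree(fx, bag, yv, 0L, mtry, nodesize, reg = TRUE)
  }
  list(trees = trees,
       schema = list(names = fx$names, is_cat = fx$is_cat,
                     levels = fx$levels))
}

.predict_forest_reg <- function(model, newdata) {
  fx <- .fx_build(as.data.frame(newdata)[, model$schema$names,
                                         drop = FALSE],
                  levels_ref = model$schema$levels)
  rows <- seq_len(fx$n)
  acc <- numeric(fx$n)
  for (tree in model$trees) {
    leaf <- .route_tree(tree, fx$cols, model$schema$is_cat, rows)
    acc <- acc + tree$value[leaf]
  }
  acc / length(model$trees)
}

# Classification forest on an arbitrary categorical response with
# class-undersampled bags (used by the iterative imputer for substrate).
.train_forest_cls <- function(X, y, k, ntree, mtry, nodesize) {
  fx <- .fx_build(X)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    bag <- undersample_bag(y, replace = TRUE)
    trees[[t]] <- .grow_tree(fx, bag, y, k, mtry, nodesize)
  }
  list(trees = trees, k = k,
       schema = list(names = fx$names, is_cat = fx$is_cat,
                     levels = fx$levels))
}

.predict_forest_cls <- function(model, newdata) {
  fx <- .fx_build(as.data.frame(newdata)[, model$schema$names,
                                         drop = FALSE],
                  levels_ref = model$schema$levels)
  rows <- seq_len(fx$n)
  acc <- matrix(0, fx$n, model$k)
  for (tree in model$trees) {
    leaf <- .route_tree(tree, fx$cols, model$schema$is_cat, rows)
    acc <- acc + tree$votes[leaf, , drop = FALSE]
  }
  max.col(acc, ties.method = "first")
}

#' Serialize a forest to JSON
#'
#' @param forest An `rf_forest`.
#' @param path Output path.
#' @param keep_bags Retain per-tree bag indices (large; default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path, keep_bags = FALSE) {
  obj <- list(params = unclass(forest$params),
              schema = forest$schema,
              classes = forest$classes,
              n_records = forest$n_records,
              trees = lapply(forest$trees, function(tr)
                list(var = tr$var, thr = tr$thr, cmask = tr$cmask,
                     left = tr$left, right = tr$right, n = tr$n,
                     votes = tr$votes)))
  if (keep_bags) obj$bags <- forest$bags
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
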