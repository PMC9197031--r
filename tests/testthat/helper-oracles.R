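# Independent oracles: brute-force implementations kept deliberately
# simple and separate from the package's code paths.

# Exhaustive Gini split scorer for a continuous predictor: tries every
# midpoint between consecutive distinct sorted values.
oracle_split_cont <- function(x, y, k, min_child = 1) {
  gini <- function(yy) {
    p <- tabulate(yy, k) / length(yy)
    1 - sum(p^2)
  }
  n <- length(x)
  xs <- sort(unique(x))
  if (length(xs) < 2) return(NULL)
  parent <- gini(y)
  best <- NULL
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- y[x <= thr]
    r <- y[x > thr]
    if (length(l) < min_child || length(r) < min_child) next
    dec <- parent - (length(l) * gini(l) + length(r) * gini(r)) / n
    if (is.null(best) || dec > best$gain + 1e-12)
      best <- list(threshold = thr, gain = dec)
  }
  if (!is.null(best) && best$gain <= 1e-12) return(NULL)
  best
}

# Exhaustive Gini scorer over every binary partition of observed levels of
# a factor (the last observed level pinned to the right side).
oracle_split_cat <- function(x, y, k, min_child = 1) {
  gini <- function(yy) {
    p <- tabulate(yy, k) / length(yy)
    1 - sum(p^2)
  }
  n <- length(x)
  lev <- levels(x)
  present <- lev[lev %in% unique(as.character(x))]
  L <- length(present)
  if (L < 2) return(NULL)
  parent <- gini(y)
  best <- NULL
  for (m in seq_len(2^(L - 1) - 1)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(L - 1) - 1)))
    left_levels <- present[c(sel, FALSE)]
    go_left <- as.character(x) %in% left_levels
    l <- y[go_left]
    r <- y[!go_left]
    if (length(l) < min_child || length(r) < min_child) next
    dec <- parent - (length(l) * gini(l) + length(r) * gini(r)) / n
    if (is.null(best) || dec > best$gain + 1e-12)
      best <- list(left_levels = left_levels, gain = dec)
  }
  if (!is.null(best) && best$gain <= 1e-12) return(NULL)
  best
}

# Brute-force Ward agglomeration by the Lance-Williams recursion, merging
# the globally closest active pair each step and recomputing every
# cluster-cluster distance with the ward.D coefficients.
oracle_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merge_sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    bestd <- Inf
    bi <- bj <- NA
    m <- length(active)
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        dij <- D[active[a], active[b]]
        if (dij < bestd - 1e-12) {
          bestd <- dij
          bi <- active[a]
          bj <- active[b]
        }
      }
    }
    heights[step] <- bestd
    for (kk in setdiff(active, c(bi, bj))) {
      ni <- sizes[bi]; nj <- sizes[bj]; nk <- sizes[kk]
      upd <- ((ni + nk) * D[bi, kk] + (nj + nk) * D[bj, kk] -
                nk * bestd) / (ni + nj + nk)
      D[bi, kk] <- D[kk, bi] <- upd
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    members[[bi]] <- sort(c(members[[bi]], members[[bj]]))
    merge_sets[[step]] <- members[[bi]]
    active <- setdiff(active, bj)
  }
  list(heights = heights, merge_sets = merge_sets)
}

# Leaf sets created at each merge step of an hclust tree.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", length(hc$height))
  for (s in seq_along(hc$height)) {
    grab <- function(ix) if (ix < 0) -ix else sets[[ix]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# Rand index between two partitions (agreement on pairs).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
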