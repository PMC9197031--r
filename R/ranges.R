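# Discriminative ranges: the spread of root-node split thresholds across
# the forest's trees, per continuous predictor, plus partial dependence of
# class voting fractions and the most-likely-group table for the
# categorical substrate.

#' Root-node split thresholds per variable
#'
#' Inspects only the root of each tree.  Roots that split a continuous
#' variable contribute their threshold to that variable's list; roots that
#' split the categorical substrate, and trees whose root is already a
#' leaf, are tallied separately so the counts over all outcomes sum to the
#' number of trees.
#'
#' @param forest An `rf_forest`.
#' @return List with `thresholds` (named list of numeric vectors, one per
#'   continuous predictor), `categorical_counts` (named, per categorical
#'   predictor) and `no_split_count`.
#' @export
root_split_points <- function(forest) {
  sch <- forest$schema
  thresholds <- stats::setNames(
    replicate(sum(!sch$is_cat), numeric(0), simplify = FALSE),
    sch$names[!sch$is_cat])
  cat_counts <- stats::setNames(integer(sum(sch$is_cat)),
                                sch$names[sch$is_cat])
  no_split <- 0L
  for (tree in forest$trees) {
    v <- tree$var[1]
    if (v == 0L) {
      no_split <- no_split + 1L
    } else if (sch$is_cat[v]) {
      cat_counts[sch$names[v]] <- cat_counts[sch$names[v]] + 1L
    } else {
      nm <- sch$names[v]
      thresholds[[nm]] <- c(thresholds[[nm]], tree$thr[1])
    }
  }
  list(thresholds = thresholds, categorical_counts = cat_counts,
       no_split_count = no_split)
}

#' Discriminative ranges of the continuous predictors
#'
#' The headline statistic: per continuous predictor, the minimum, mean and
#' maximum of its root-node split thresholds across the forest, together
#' with the number of trees rooting on it.  The [min, max] interval is the
#' gradient region where the forest's discrimination between species
#' groups is most apparent; the wider it is, the more variable the
#' split-point.  Variables that never occupy a root have count 0 and `NA`
#' summaries.
#'
#' @param forest An `rf_forest`.
#' @return A `split_range_summary`: data frame with columns `variable`,
#'   `count`, `min`, `mean`, `max`; attributes `"thresholds"` (full lists),
#'   `"categorical_counts"` and `"no_split_count"`.
#' @export
discriminative_ranges <- function(forest) {
  rs <- root_split_points(forest)
  out <- do.call(rbind, lapply(names(rs$thresholds), function(v) {
    th <- rs$thresholds[[v]]
    if (length(th) == 0)
      data.frame(variable = v, count = 0L, min = NA_real_,
                 mean = NA_real_, max = NA_real_)
    else
      data.frame(variable = v, count = length(th), min = min(th),
                 mean = mean(th), max = max(th))
  }))
  rownames(out) <- NULL
  structure(out, class = c("split_range_summary", "data.frame"),
            thresholds = rs$thresholds,
            categorical_counts = rs$categorical_counts,
            no_split_count = rs$no_split_count)
}

#' Partial dependence of voting fractions on one continuous predictor
#'
#' For each grid value `g` the predictor is set to `g` in every record of
#' the dataset and the voting fractions are averaged over records: the
#' marginal effect of the predictor on the model's per-group vote.  The
#' default grid is 25 quantile-spaced points between the 1st and 99th
#' percentile of the observed values (avoiding tail extrapolation);
#' log-scaled display is a plotting concern.
#'
#' @param forest An `rf_forest`.
#' @param ds A complete `model_dataset`.
#' @param variable Name of a continuous predictor.
#' @param grid Optional increasing numeric grid (overrides `n_grid`).
#' @param n_grid Number of quantile-spaced grid points (default 25).
#' @return A `pdp_curve`: data frame with `grid` and one voting-fraction
#'   column per group (rows sum to 1).
#' @export
partial_dependence <- function(forest, ds, variable, grid = NULL,
                               n_grid = 25) {
  stopifnot(variable %in% forest$schema$names,
            !forest$schema$is_cat[match(variable, forest$schema$names)])
  x <- ds$X[[variable]]
  if (is.null(grid)) {
    grid <- unique(stats::quantile(x, probs = seq(0.01, 0.99,
                                                  length.out = n_grid),
                                   names = FALSE, type = 7))
  }
  if (length(grid) == 0) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  k <- length(forest$classes)
  curves <- matrix(0, length(grid), k)
  X <- ds$X
  for (i in seq_along(grid)) {
    X[[variable]] <- grid[i]
    curves[i, ] <- colMeans(predict_votes(forest, X))
  }
  out <- data.frame(grid = grid)
  out[paste0("group", seq_len(k))] <- as.data.frame(curves)
  structure(out, class = c("pdp_curve", "data.frame"), variable = variable)
}

#' Most likely group per substrate category
#'
#' The categorical analogue of a partial dependence curve: for each of the
#' 7 substrate categories, substrate is set to that category in every
#' record, voting fractions are averaged, and the top-voted group is
#' reported (ties resolved to the lowest label and flagged).
#'
#' @param forest An `rf_forest`.
#' @param ds A complete `model_dataset`.
#' @param variable Name of the categorical predictor (default
#'   `"substrate"`).
#' @return Data frame with one row per category: `category`, `top_group`,
#'   `vote_fraction`, `tie`.
#' @export
substrate_top_group <- function(forest, ds, variable = "substrate") {
  j <- match(variable, forest$schema$names)
  stopifnot(!is.na(j), forest$schema$is_cat[j])
  lv <- forest$schema$levels[[j]]
  X <- ds$X
  rows <- lapply(lv, function(cat) {
    X[[variable]] <- factor(cat, levels = lv)
    v <- colMeans(predict_votes(forest, X))
    top <- which.max(v)
    data.frame(category = cat, top_group = top, vote_fraction = v[top],
               tie = sum(v == v[top]) > 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine ranges and partial-dependence curves into one report
#'
#' Per continuous predictor: the PDP curve plus the (min, mean, max)
#' root-split overlay, mirroring the usual display of a shaded split-point
#' band with dotted min/max and dashed mean lines.
#'
#' @param ranges A [discriminative_ranges()] summary.
#' @param pdps Named list of [partial_dependence()] curves (names =
#'   variables), computed on the same forest.
#' @return Named list per variable: `curve`, `min`, `mean`, `max`,
#'   `count`, `no_root_splits` flag.
#' @export
range_overlay_report <- function(ranges, pdps) {
  if (!setequal(names(pdps), ranges$variable))
    stop("PDP variables do not match the range summary")
  out <- lapply(ranges$variable, function(v) {
    r <- ranges[ranges$variable == v, ]
    list(variable = v, curve = as.data.frame(pdps[[v]]),
         min = r$min, mean = r$mean, max = r$max, count = r$count,
         no_root_splits = r$count == 0)
  })
  stats::setNames(out, ranges$variable)
}

#' Plot a partial-dependence curve with its discriminative range
#'
#' Voting-fraction curves per group on a log-scaled gradient axis, with
#' the root-split range shaded and the min/max (dotted) and mean (dashed)
#' thresholds overlaid.  Requires ggplot2.
#'
#' @param pdp A [partial_dependence()] curve.
#' @param ranges Optional [discriminative_ranges()] summary for the
#'   overlay.
#' @param log_x Log-scale the gradient axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_pdp <- function(pdp, ranges = NULL, log_x = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_pdp requires the ggplot2 package")
  v <- attr(pdp, "variable")
  df <- as.data.frame(pdp)
  long <- stats::reshape(df, direction = "long",
                         varying = setdiff(names(df), "grid"),
                         v.names = "vote", timevar = "group",
                         times = setdiff(names(df), "grid"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$grid, y = .data$vote,
                                          colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(v, " (", ENV_UNITS[[v]], ")"),
                  y = "voting fraction")
  if (!is.null(ranges)) {
    r <- ranges[ranges$variable == v, ]
    if (r$count > 0) {
      p <- p +
        ggplot2::annotate("rect", xmin = r$min, xmax = r$max,
                          ymin = -Inf, ymax = Inf, alpha = 0.15) +
        ggplot2::geom_vline(xintercept = c(r$min, r$max),
                            linetype = "dotted") +
        ggplot2::geom_vline(xintercept = r$mean, linetype = "dashed")
    }
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}
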