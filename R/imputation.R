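# The two missing-value strategies compared at the model level: simple
# median/mode substitution and an iterative forest-based imputer of the
# missForest family (initialize -> cycle over variables in increasing
# missingness order -> stop when the change statistic first increases,
# returning the previous state).

#' Median / mode imputation
#'
#' Continuous missing cells are replaced by the column median of the
#' observed values; the categorical substrate by its most frequent
#' category (ties to the first level).  Observed cells are untouched.
#'
#' @param sites A `site_table`.
#' @return List with `sites` (complete) and `report` (method, per-variable
#'   imputed-cell counts).
#' @export
impute_median_mode <- function(sites) {
  imputed <- integer(0)
  for (v in ENV_VARS) {
    x <- sites[[v]]
    if (all(is.na(x))) stop("variable '", v, "' is fully missing")
    miss <- is.na(x)
    sites[[v]][miss] <- stats::median(x[!miss])
    imputed[v] <- sum(miss)
  }
  s <- sites$substrate
  if (all(is.na(s))) stop("substrate is fully missing")
  miss <- is.na(s)
  sites$substrate[miss] <-
    SUBSTRATE_LEVELS[which.max(tabulate(as.integer(s), 7))]
  imputed["substrate"] <- sum(miss)
  list(sites = sites,
       report = list(method = "median_mode", imputed = as.list(imputed),
                     iterations = 0L, trace = list()))
}

#' Iterative forest imputation
#'
#' The iterative scheme of forest-based imputation: initialise by
#' median/mode; visit variables in increasing missingness order; for each
#' incompletely observed variable fit a forest of that variable on all
#' others using the rows where it is observed (regression forest with mean
#' leaves for continuous variables; classification forest with per-class
#' undersampled bags for the categorical substrate) and overwrite its
#' missing cells with the forest's predictions.  Iterate until the change
#' statistic -- normalised squared change over the continuous block,
#' disagreement fraction over the categorical block -- first increases for
#' either block, and return the state before the increase.  Regression
#' predictions are floored at zero (flagged in the report) so imputed
#' concentrations stay physical.
#'
#' @param sites A `site_table` with missing cells.
#' @param ntree Trees per internal forest (published configuration: 200).
#' @param max_iter Maximum number of sweeps (default 10).
#' @param seed Integer seed.
#' @param mtry,nodesize Internal forest controls; defaults are the
#'   conventional regression-forest choices (`ceiling(p/3)` candidates,
#'   small terminal nodes).
#' @return List with `sites` (complete) and `report` (method, imputed
#'   counts, iterations run, per-iteration convergence trace, number of
#'   floored predictions).
#' @export
impute_iterative_forest <- function(sites, ntree = 200, max_iter = 10,
                                    seed = 1, mtry = NULL, nodesize = 5) {
  all_vars <- c(ENV_VARS, "substrate")
  miss_mask <- lapply(all_vars, function(v) is.na(sites[[v]]))
  names(miss_mask) <- all_vars
  n_miss <- vapply(miss_mask, sum, 0L)
  if (length(all_vars) < 2) stop("need at least two variables to impute")
  for (v in all_vars)
    if (all(miss_mask[[v]])) stop("variable '", v, "' is fully missing")
  p <- length(all_vars) - 1L
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  init <- impute_median_mode(sites)
  cur <- init$sites
  if (sum(n_miss) == 0)
    return(list(sites = cur,
                report = list(method = "iterative_forest",
                              imputed = as.list(n_miss), iterations = 0L,
                              trace = list(), floored = 0L)))
  set.seed(seed)
  visit <- all_vars[order(n_miss)]
  visit <- visit[n_miss[visit] > 0]
  prev <- cur
  prev_stat <- c(cont = Inf, cat = Inf)
  trace <- list()
  floored <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    old <- cur
    for (v in visit) {
      obs <- !miss_mask[[v]]
      Xo <- as.data.frame(cur)[, setdiff(all_vars, v), drop = FALSE]
      if (v == "substrate") {
        y <- as.integer(cur$substrate[obs])
        # drop classes below 2 observed records: undersampling needs them
        keep <- tabulate(y, 7) > 0
        ymap <- cumsum(keep)
        model <- .train_forest_cls(Xo[obs, , drop = FALSE], ymap[y],
                                   k = sum(keep), ntree, mtry, nodesize)
        pr <- .predict_forest_cls(model, Xo[miss_mask[[v]], , drop = FALSE])
        cur$substrate[miss_mask[[v]]] <- SUBSTRATE_LEVELS[which(keep)][pr]
      } else {
        model <- .train_forest_reg(Xo[obs, , drop = FALSE],
                                   as.numeric(cur[[v]][obs]),
                                   ntree, mtry, nodesize)
        pr <- .predict_forest_reg(model, Xo[miss_mask[[v]], , drop = FALSE])
        below <- pr < 0
        floored <- floored + sum(below)
        pr[below] <- 0
        cur[[v]][miss_mask[[v]]] <- pr
      }
    }
    num <- den <- 0
    for (v in ENV_VARS) {
      m <- miss_mask[[v]]
      if (!any(m)) next
      num <- num + sum((cur[[v]][m] - old[[v]][m])^2)
      den <- den + sum(cur[[v]][m]^2)
    }
    stat_cont <- if (den > 0) num / den else 0
    m <- miss_mask[["substrate"]]
    stat_cat <- if (any(m))
      mean(cur$substrate[m] != old$substrate[m]) else 0
    trace[[iter]] <- list(iteration = iter, continuous = stat_cont,
                          categorical = stat_cat)
    if (stat_cont > prev_stat["cont"] || stat_cat > prev_stat["cat"]) {
      cur <- prev  # criterion increased: keep the previous sweep's state
      iter <- iter - 1L
      break
    }
    prev <- cur
    prev_stat <- c(cont = stat_cont, cat = stat_cat)
  }
  list(sites = cur,
       report = list(method = "iterative_forest", imputed = as.list(n_miss),
                     iterations = iter, trace = trace, floored = floored))
}
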