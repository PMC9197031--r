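# Metrics (accuracy, Cohen's kappa with interpretation bands), data
# splitting, out-of-bag kappa-thresholded selection of the number of
# groups, the holdout sanity check, and stratified k-fold cross-validation.

#' Confusion matrix
#'
#' @param true,pred Integer labels in `1..k`, equal length.
#' @param k Number of classes (default: largest label seen).
#' @return k x k integer matrix, rows = true group, columns = predicted.
#' @export
confusion <- function(true, pred, k = max(c(true, pred))) {
  if (length(true) != length(pred))
    stop("true and predicted label vectors differ in length")
  ok <- !is.na(pred)
  cm <- matrix(0L, k, k,
               dimnames = list(true = paste0("g", seq_len(k)),
                               pred = paste0("g", seq_len(k))))
  tab <- table(factor(true[ok], levels = seq_len(k)),
               factor(pred[ok], levels = seq_len(k)))
  cm[] <- as.integer(tab)
  cm
}

#' Classification accuracy
#'
#' Fraction of records on the diagonal of the confusion matrix: the
#' percentage of species occurrences classified into the correct group.
#'
#' @param cm Confusion matrix (see [confusion()]).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/total` and expected chance agreement
#' `p_e = sum_i row_i * col_i / total^2`.
#'
#' @param cm Confusion matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) stop("degenerate confusion matrix: chance agreement is 1")
  (po - pe) / (1 - pe)
}

#' Interpretation band for a kappa value
#'
#' The conventional agreement bands: `< 0` poor; `0-0.19` slight;
#' `0.20-0.39` fair; `0.40-0.59` moderate; `0.60-0.79` substantial;
#' `>= 0.80` almost perfect.
#'
#' @param kappa Kappa value in `[-1, 1]`.
#' @return Character label, e.g. `"fair agreement"`.
#' @export
kappa_band <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa < 0) "poor agreement"
  else if (kappa < 0.20) "slight agreement"
  else if (kappa < 0.40) "fair agreement"
  else if (kappa < 0.60) "moderate agreement"
  else if (kappa < 0.80) "substantial agreement"
  else "almost perfect agreement"
}

# Convenience: OOB accuracy and kappa of a trained forest.
oob_metrics <- function(forest, ds) {
  oob <- oob_predict(forest, ds)
  cm <- confusion(ds$y[oob$covered], oob$pred[oob$covered], k = ds$k)
  list(accuracy = accuracy(cm), kappa = cohens_kappa(cm), confusion = cm,
       n_uncovered = sum(!oob$covered))
}

# Subset a model_dataset by record indices.
.ds_subset <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
                 species_id = ds$species_id[idx],
                 site_id = ds$site_id[idx], k = ds$k),
            class = "model_dataset")
}

#' Random train / holdout split of the record-level dataset
#'
#' Record-level random partition.  If a group is absent from either part
#' the split is redrawn (up to `max_tries`, then an error), since the
#' forest needs every class in training and the metrics need every class
#' scored.
#'
#' @param ds A `model_dataset`.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @param stratify Stratify the split by group (default `FALSE`).
#' @param max_tries Redraw budget for unlucky splits.
#' @return List with `train` and `holdout` (`model_dataset`s) and the
#'   record index vectors `train_idx`, `holdout_idx`; attribute `"tries"`
#'   records redraws.
#' @export
train_holdout_split <- function(ds, train_frac = 0.8, seed = 1,
                                stratify = FALSE, max_tries = 100) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- length(ds$y)
  set.seed(seed)
  for (tries in seq_len(max_tries)) {
    if (stratify) {
      tr <- unlist(lapply(seq_len(ds$k), function(g) {
        idx <- which(ds$y == g)
        sample(idx, round(length(idx) * train_frac))
      }), use.names = FALSE)
    } else {
      tr <- sample.int(n, round(n * train_frac))
    }
    tr <- sort(tr)
    ho <- setdiff(seq_len(n), tr)
    if (all(seq_len(ds$k) %in% ds$y[tr]) &&
        all(seq_len(ds$k) %in% ds$y[ho])) {
      out <- list(train = .ds_subset(ds, tr), holdout = .ds_subset(ds, ho),
                  train_idx = tr, holdout_idx = ho)
      attr(out, "tries") <- tries
      return(out)
    }
  }
  stop("a group is too small to appear in both the training and holdout ",
       "fraction")
}

#' Select the number of species groups by the OOB kappa threshold
#'
#' Scans cluster counts upward from `k_min`: for each k the dendrogram
#' (built from the full presence matrix) is cut into k groups, the
#' record-level dataset is assembled, a forest is trained on the training
#' fraction, and the out-of-bag Cohen's kappa is computed.  The scan stops
#' at the first k whose kappa drops below `kappa_min`; the selected count
#' is the k immediately before the drop.  If kappa is already below the
#' threshold at `k_min` the selection is flagged `"none"`.
#'
#' @param pm A `presence_matrix` (clustering uses all sites).
#' @param sites A complete (imputed) `site_table`.
#' @param params A [forest_params()].
#' @param kappa_min Kappa threshold (default 0.3).
#' @param k_min,k_max Scan range (defaults 2 and `min(n_species, 20)`; the
#'   full scan to the species count is reachable by setting `k_max`).
#' @param train_frac Training fraction for each k's forest (default 0.8).
#' @param seed Seed for the per-k train/holdout splits.
#' @param metric_fn Optional stub for testing the stopping rule: a
#'   `function(k, assignment)` returning `list(accuracy=, kappa=)` used in
#'   place of the forest.
#' @return A `selection_trace`: list with `trace` (data frame of k,
#'   oob_accuracy, oob_kappa, band), `selected_k` (integer or `NA`),
#'   `reason`.
#' @export
select_n_groups <- function(pm, sites, params = forest_params(),
                            kappa_min = 0.3, k_min = 2,
                            k_max = min(nrow(pm), 20), train_frac = 0.8,
                            seed = 1, metric_fn = NULL) {
  dend <- ward_linkage(jaccard_distances(pm))
  rows <- list()
  selected <- NA_integer_
  reason <- "scan exhausted without dropping below threshold"
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, k_max - k_min + 1)
  for (k in k_min:k_max) {
    assignment <- cut_dendrogram(dend, k)
    if (is.null(metric_fn)) {
      ds <- build_model_dataset(pm, sites, assignment)
      sp <- train_holdout_split(ds, train_frac,
                                seed = split_seeds[k - k_min + 1])
      forest <- train_forest(sp$train, params)
      m <- oob_metrics(forest, sp$train)
    } else {
      m <- metric_fn(k, assignment)
    }
    rows[[length(rows) + 1]] <-
      data.frame(k = k, oob_accuracy = m$accuracy, oob_kappa = m$kappa,
                 band = kappa_band(m$kappa))
    if (m$kappa < kappa_min) {
      if (k == k_min) {
        selected <- NA_integer_
        reason <- sprintf("none: kappa %.3f < %.2f already at k = %d",
                          m$kappa, kappa_min, k_min)
      } else {
        selected <- k - 1L
        reason <- sprintf("kappa dropped below %.2f at k = %d", kappa_min, k)
      }
      break
    }
    selected <- k
  }
  structure(list(trace = do.call(rbind, rows), selected_k = selected,
                 reason = reason),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  print(x$trace, row.names = FALSE)
  cat("selected k:", ifelse(is.na(x$selected_k), "none", x$selected_k),
      "--", x$reason, "\n")
  invisible(x)
}

#' Compare OOB metrics with holdout metrics
#'
#' The overfitting sanity check: the model generalises acceptably when the
#' holdout accuracy deviates from the OOB accuracy by at most `tol`
#' (default 5 percentage points).
#'
#' @param oob,holdout Lists with `accuracy` and `kappa`.
#' @param tol Tolerated absolute accuracy deviation.
#' @return List with `pass`, `delta_accuracy`, `delta_kappa`.
#' @export
holdout_check <- function(oob, holdout, tol = 0.05) {
  da <- abs(oob$accuracy - holdout$accuracy)
  dk <- abs(oob$kappa - holdout$kappa)
  list(pass = da <= tol, delta_accuracy = da, delta_kappa = dk)
}

# Metrics of a forest on an external (holdout / CV) dataset.
holdout_metrics <- function(forest, ds) {
  votes <- predict_votes(forest, ds)
  cm <- confusion(ds$y, attr(votes, "pred"), k = ds$k)
  list(accuracy = accuracy(cm), kappa = cohens_kappa(cm), confusion = cm)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by group (per-stratum fold sizes differ by at most
#' one), so no fold is missing a class.  Each fold is scored by a forest
#' trained on the remaining folds.
#'
#' @param ds A `model_dataset`.
#' @param params A [forest_params()].
#' @param n_folds Number of folds (default 10); every group must have at
#'   least `n_folds` records.
#' @param seed Integer seed for fold assignment.
#' @return List with `folds` (per-fold data frame of accuracy and kappa)
#'   and `summary` (mean and sd of both metrics).
#' @export
kfold_cv <- function(ds, params = forest_params(), n_folds = 10, seed = 1) {
  stopifnot(n_folds >= 2)
  counts <- tabulate(ds$y, ds$k)
  if (any(counts < n_folds))
    stop("group(s) with fewer than ", n_folds,
         " records; use fewer folds")
  set.seed(seed)
  fold <- integer(length(ds$y))
  for (g in seq_len(ds$k)) {
    idx <- which(ds$y == g)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  res <- lapply(seq_len(n_folds), function(f) {
    forest <- train_forest(.ds_subset(ds, which(fold != f)), params)
    m <- holdout_metrics(forest, .ds_subset(ds, which(fold == f)))
    data.frame(fold = f, accuracy = m$accuracy, kappa = m$kappa)
  })
  folds <- do.call(rbind, res)
  list(folds = folds,
       summary = list(accuracy_mean = mean(folds$accuracy),
                      accuracy_sd = stats::sd(folds$accuracy),
                      kappa_mean = mean(folds$kappa),
                      kappa_sd = stats::sd(folds$kappa)),
       fold_assignment = fold)
}
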