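# Species co-occurrence grouping: binary Jaccard distances between species
# presence profiles, Ward agglomeration on the unsquared distances (the
# "ward.D" convention), and hierarchical cuts into 2..n groups.

#' Jaccard distances between species presence profiles
#'
#' `d(a, b) = 1 - |sites(a) & sites(b)| / |sites(a) | sites(b)|` computed on
#' the boolean presence matrix.  Species with all-zero rows are rejected
#' (the union ratio is undefined; the occurrence filter removes them
#' upstream).
#'
#' @param pm A `presence_matrix` (species x sites).
#' @return A `dist` object labelled with species ids.
#' @export
jaccard_distances <- function(pm) {
  stopifnot(nrow(pm) >= 2)
  if (any(rowSums(pm) == 0))
    stop("presence matrix has all-zero species row(s); filter first")
  vegan::vegdist(pm * 1, method = "jaccard", binary = TRUE)
}

#' Ward agglomeration of a distance matrix
#'
#' Agglomerative clustering with the Lance-Williams Ward update applied to
#' the distances as given (no squaring of the input; `hclust`'s "ward.D"),
#' the reading of "Ward's criterion" used throughout this pipeline.  A
#' squared-input variant ("ward.D2") is available for sensitivity
#' analysis.
#'
#' @param d A `dist` object (e.g. from [jaccard_distances()]).
#' @param squared If `TRUE` use the squared-distance Ward variant.
#' @return An `hclust` dendrogram.
#' @export
ward_linkage <- function(d, squared = FALSE) {
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  stats::hclust(d, method = if (squared) "ward.D2" else "ward.D")
}

#' Cut a dendrogram into k groups
#'
#' Standard hierarchical cut (undo the last `k - 1` merges); labels are
#' assigned in leaf (input) order, so group 1 always contains the first
#' species, giving stable labels for downstream reporting.
#'
#' @param dend An `hclust` object.
#' @param k Number of groups, `1 <= k <=` number of species.
#' @return Named integer vector species_id -> label in `1..k`.
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  stats::cutree(dend, k = k)
}

#' Cut a dendrogram at every k in a range
#'
#' @param dend An `hclust` object.
#' @param k_min,k_max Range of cluster counts (defaults 2 and the number of
#'   species, the full scan in which the final cut is all singletons).
#' @return Named list of assignments, one per k (`"k2"`, `"k3"`, ...);
#'   cuts are nested (groups at k are unions of groups at k + 1).
#' @export
scan_cluster_range <- function(dend, k_min = 2,
                               k_max = length(dend$labels)) {
  stopifnot(k_min >= 2, k_max >= k_min, k_max <= length(dend$labels))
  ks <- k_min:k_max
  stats::setNames(lapply(ks, function(k) cut_dendrogram(dend, k)),
                  paste0("k", ks))
}

#' Serialize a dendrogram's merge list
#'
#' @param dend An `hclust` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path) {
  jsonlite::write_json(
    list(labels = dend$labels,
         merges = lapply(seq_along(dend$height), function(i)
           list(left = dend$merge[i, 1], right = dend$merge[i, 2],
                height = dend$height[i])),
         method = dend$method),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
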