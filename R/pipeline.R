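# Orchestration of the full workflow: load or simulate a survey, filter
# species, cluster co-occurrences, impute the environmental table by both
# strategies, select the number of groups, train the final forests,
# holdout-check, cross-validate, and extract discriminative ranges, PDP
# curves and the substrate table.  Every stage artifact is serialized so
# the stage functions can be re-run in isolation; a JSON-lines log records
# stage names, seeds and row counts.

#' Pipeline configuration
#'
#' Either CSV `sites` / `occurrences` paths or a synthetic survey spec.
#' All randomness flows from the single mandatory `seed` via named child
#' seeds (simulation, splitting, bagging, imputation, CV); clustering is
#' deterministic and consumes none.
#'
#' @param sites,occurrences Paths to input CSVs (`NULL` to simulate).
#' @param n_sites,n_species Synthetic survey dimensions (used when no
#'   paths are given).
#' @param spec [gradient_spec()] for the synthetic survey.
#' @param niches Planted niches for the synthetic survey
#'   ([default_niches()]).
#' @param min_sites Species occurrence filter (default 25).
#' @param aquatic_only Keep only aquatic-flagged records.
#' @param imputation Character vector of tracks to run, subset of
#'   `c("median", "forest")` (default both, the comparison design).
#' @param impute_ntree Trees per internal imputation forest (default 200).
#' @param params [forest_params()] for the selection scan and final model.
#' @param kappa_min OOB kappa threshold for group-count selection.
#' @param k_max Upper bound of the cluster scan.
#' @param train_frac Training fraction (default 0.8).
#' @param n_folds Cross-validation folds (default 10).
#' @param pdp_grid Number of partial-dependence grid points (default 25).
#' @param seed Master seed (mandatory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sites = NULL, occurrences = NULL,
                            n_sites = 400, n_species = 24,
                            spec = gradient_spec(),
                            niches = default_niches(), min_sites = 25,
                            aquatic_only = FALSE,
                            imputation = c("median", "forest"),
                            impute_ntree = 200,
                            params = forest_params(), kappa_min = 0.3,
                            k_max = 20, train_frac = 0.8, n_folds = 10,
                            pdp_grid = 25, seed = 1) {
  stopifnot(all(imputation %in% c("median", "forest")),
            length(seed) == 1, is.finite(seed))
  if (!is.null(sites) && !file.exists(sites))
    stop("sites file not found: ", sites)
  if (!is.null(occurrences) && !file.exists(occurrences))
    stop("occurrences file not found: ", occurrences)
  structure(list(sites = sites, occurrences = occurrences,
                 n_sites = n_sites, n_species = n_species, spec = spec,
                 niches = niches,
                 min_sites = min_sites, aquatic_only = aquatic_only,
                 imputation = imputation, impute_ntree = impute_ntree,
                 params = params, kappa_min = kappa_min, k_max = k_max,
                 train_frac = train_frac, n_folds = n_folds,
                 pdp_grid = pdp_grid, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value file mirroring the arguments of [pipeline_config()];
#' nested `params:` block for the forest hyper-parameters.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fp <- do.call(forest_params, if (is.null(y$params)) list() else y$params)
  y$params <- fp
  keep <- intersect(names(y), names(formals(pipeline_config)))
  do.call(pipeline_config, y[keep])
}

.log_stage <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full pipeline
#'
#' Executes: load/simulate -> species filter -> presence matrix ->
#' Jaccard distances -> Ward dendrogram -> imputation (each configured
#' track) -> kappa-thresholded group-count selection -> final forest ->
#' holdout check -> k-fold CV -> discriminative ranges, PDP curves and
#' substrate table -> serialized reports.  Reruns with the same
#' configuration produce byte-identical CSV artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the per-track results (`selection`,
#'   `forest`, `metrics`, `ranges`, `pdps`, `substrate`) plus the shared
#'   stage objects (`bundle`, `pm`, `dend`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline_log.jsonl"), open = "wt")
  on.exit(close(log_con))
  set.seed(cfg$seed)
  child <- as.list(sample.int(.Machine$integer.max - 1L, 4))
  names(child) <- c("simulate", "split", "impute", "cv")

  # --- data ---
  if (is.null(cfg$sites)) {
    bundle <- simulate_survey(cfg$n_sites, cfg$n_species, spec = cfg$spec,
                              niches = cfg$niches,
                              seed = child$simulate)
    write_survey(bundle, out_dir)
    sites_raw <- bundle$sites
    occ <- bundle$occurrences
    .log_stage(log_con, "simulate", seed = child$simulate,
               n_sites = nrow(sites_raw), n_records = nrow(occ))
  } else {
    bundle <- NULL
    sites_raw <- read_site_table(cfg$sites)
    occ <- read_occurrences(cfg$occurrences)
    .log_stage(log_con, "load", n_sites = nrow(sites_raw),
               n_records = nrow(occ))
  }

  # --- filter + clustering (all sites, observed data) ---
  pm <- build_presence_matrix(occ, cfg$min_sites, cfg$aquatic_only)
  .log_stage(log_con, "filter", min_sites = cfg$min_sites,
             n_species = nrow(pm), n_records = sum(pm))
  d <- jaccard_distances(pm)
  dend <- ward_linkage(d)
  utils::write.csv(as.matrix(d), file.path(out_dir, "distances.csv"))
  write_dendrogram(dend, file.path(out_dir, "dendrogram.json"))
  .log_stage(log_con, "cluster", n_species = nrow(pm))

  tracks <- list()
  for (method in cfg$imputation) {
    imp <- if (method == "median") impute_median_mode(sites_raw)
    else impute_iterative_forest(sites_raw, ntree = cfg$impute_ntree,
                                 seed = child$impute)
    jsonlite::write_json(imp$report,
                         file.path(out_dir,
                                   paste0("imputation_report_", method,
                                          ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .log_stage(log_con, "impute", method = method,
               iterations = imp$report$iterations)

    sel <- select_n_groups(pm, imp$sites, cfg$params,
                           kappa_min = cfg$kappa_min,
                           k_max = min(cfg$k_max, nrow(pm)),
                           train_frac = cfg$train_frac, seed = child$split)
    utils::write.csv(sel$trace,
                     file.path(out_dir,
                               paste0("selection_trace_", method, ".csv")),
                     row.names = FALSE)
    .log_stage(log_con, "select_k", method = method,
               selected = ifelse(is.na(sel$selected_k), "none",
                                 sel$selected_k))
    if (is.na(sel$selected_k)) {
      tracks[[method]] <- list(selection = sel)
      next
    }
    k <- sel$selected_k
    assignment <- cut_dendrogram(dend, k)
    utils::write.csv(data.frame(species_id = names(assignment),
                                label = as.integer(assignment)),
                     file.path(out_dir,
                               paste0("groups_k", k, "_", method, ".csv")),
                     row.names = FALSE)
    ds <- build_model_dataset(pm, imp$sites, assignment)
    sp <- train_holdout_split(ds, cfg$train_frac, seed = child$split)
    forest <- train_forest(sp$train, cfg$params)
    m_oob <- oob_metrics(forest, sp$train)
    m_ho <- holdout_metrics(forest, sp$holdout)
    check <- holdout_check(m_oob, m_ho)
    cv <- kfold_cv(ds, cfg$params, n_folds = cfg$n_folds, seed = child$cv)
    .log_stage(log_con, "train", method = method, k = k,
               seed = cfg$params$seed, ntree = cfg$params$ntree,
               oob_accuracy = m_oob$accuracy, oob_kappa = m_oob$kappa,
               holdout_pass = check$pass)

    ranges <- discriminative_ranges(forest)
    utils::write.csv(as.data.frame(ranges),
                     file.path(out_dir, paste0("ranges_", method, ".csv")),
                     row.names = FALSE)
    pdps <- lapply(stats::setNames(nm = ranges$variable), function(v)
      partial_dependence(forest, ds, v, n_grid = cfg$pdp_grid))
    for (v in names(pdps))
      utils::write.csv(as.data.frame(pdps[[v]]),
                       file.path(out_dir,
                                 paste0("pdp_", v, "_", method, ".csv")),
                       row.names = FALSE)
    sub <- substrate_top_group(forest, ds)
    utils::write.csv(sub,
                     file.path(out_dir,
                               paste0("substrate_groups_", method, ".csv")),
                     row.names = FALSE)
    .log_stage(log_con, "ranges", method = method)

    tracks[[method]] <- list(
      selection = sel, k = k, forest = forest,
      metrics = list(oob = m_oob[c("accuracy", "kappa")],
                     holdout = m_ho[c("accuracy", "kappa")],
                     holdout_check = check, cv = cv$summary),
      ranges = ranges, pdps = pdps, substrate = sub)
  }

  metrics <- lapply(tracks, function(tr)
    if (is.null(tr$metrics)) list(selected_k = "none") else
      c(list(selected_k = tr$k), tr$metrics))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_sidecar(file.path(out_dir, "run"),
                list(schema_version = "1.0", seed = cfg$seed,
                     min_sites = cfg$min_sites,
                     imputation = cfg$imputation,
                     ntree = cfg$params$ntree, mtry = cfg$params$mtry,
                     nodesize = cfg$params$nodesize,
                     kappa_min = cfg$kappa_min,
                     train_frac = cfg$train_frac, n_folds = cfg$n_folds))
  invisible(list(tracks = tracks, bundle = bundle, pm = pm, dend = dend))
}
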