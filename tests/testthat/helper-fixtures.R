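# Shared fixtures.  Expensive objects (default bundle, trained forests)
# are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Tiny hand-written site table (3 sites, one missing depth).
tiny_sites_df <- function() {
  data.frame(
    site_id = c("a", "b", "c"),
    alkalinity = c(1.2, 2.5, 0.4),
    velocity = c(0.2, 0.5, 0.8),
    nitrate = c(0.5, 2.5, 10),
    total_phosphorus = c(30, 110, 500),
    width = c(3, 8, 40),
    depth = c(0.2, NA, 1.0),
    substrate = c("Sand", "Gravel", NA),
    stringsAsFactors = FALSE)
}

# Wrap predictors + labels as a model_dataset without going through the
# survey machinery (used for deterministic-rule datasets).
make_ds <- function(X, y) {
  structure(list(X = X, y = as.integer(y),
                 species_id = paste0("r", seq_along(y)),
                 site_id = paste0("r", seq_along(y)),
                 k = max(y)),
            class = "model_dataset")
}

# Default desk-scale planted bundle and objects derived from it.
default_bundle <- function() cached("bundle", simulate_survey(seed = 11))

default_pm <- function()
  cached("pm", build_presence_matrix(default_bundle()$occurrences, 25))

default_sites_median <- function()
  cached("sites_median", impute_median_mode(default_bundle()$sites)$sites)

# Record-level dataset labelled with the planted truth groups.
default_ds <- function() cached("ds", {
  b <- default_bundle()
  pm <- default_pm()
  build_model_dataset(pm, default_sites_median(),
                      b$truth$species_group[rownames(pm)])
})

default_split <- function()
  cached("split", train_holdout_split(default_ds(), 0.8, seed = 21))

# Forest at the published mtry/nodesize, desk-scale ntree, trained on the
# 80% training fraction.
default_forest <- function() cached("forest", {
  train_forest(default_split()$train,
               forest_params(ntree = 300, mtry = 1, nodesize = 200,
                             seed = 3))
})

# Perfectly separable 4-group dataset: labels are a deterministic rule of
# total phosphorus and substrate coarseness, so a forest should approach
# perfect OOB accuracy.
separable_ds <- function(n = 600, seed = 5) {
  cached(paste0("sep", n, "_", seed), {
    sites <- generate_sites(gradient_spec(), n, seed)
    coarse <- sites$substrate %in% c("Gravel", "Gravel and boulder",
                                     "Rock and gravel", "Sand and gravel")
    y <- 1L + 2L * (sites$total_phosphorus > 110) + 1L * coarse
    make_ds(as.data.frame(sites)[, c(env_variables(), "substrate")], y)
  })
}

# Two-group bundle whose only signal is a single threshold on total
# phosphorus.  softness = 0 is the hard-step limit (used for occupancy
# limit tests); the recovery bundle uses a sharp logistic (softness 10
# ug L-1, ~8% of the threshold) so that split-points scatter on both
# sides of the planted value instead of collapsing onto the empirical
# gap between the two classes.
step_niches <- function(threshold = 130, softness = 0) {
  list(
    niche_spec(1L, list(total_phosphorus = list(direction = "below",
                                                threshold = threshold,
                                                softness = softness)),
               baseline = 0.6),
    niche_spec(2L, list(total_phosphorus = list(direction = "above",
                                                threshold = threshold,
                                                softness = softness)),
               baseline = 0.6))
}

step_bundle_forest <- function(seed, ntree = 400, n_sites = 300,
                               n_species = 8) {
  b <- simulate_survey(n_sites, n_species,
                       niches = step_niches(softness = 10),
                       seed = seed, missing = FALSE)
  pm <- build_presence_matrix(b$occurrences, min_sites = 10)
  ds <- build_model_dataset(pm, b$sites_complete,
                            b$truth$species_group[rownames(pm)])
  forest <- train_forest(ds, forest_params(ntree = ntree, mtry = 1,
                                           nodesize = 60, seed = seed + 1))
  list(ds = ds, forest = forest)
}

# Hand-built stub trees/forests for introspection tests.
stub_leaf_tree <- function(votes) {
  structure(list(var = 0L, thr = 0, cmask = 0L, left = 0L, right = 0L,
                 n = 1L, votes = matrix(votes, 1)),
            class = "rf_tree")
}

# Depth-1 tree splitting numeric variable v at thr, pure leaves (class 1
# left, class 2 right).
stub_split_tree <- function(v, thr, k = 2) {
  votes <- matrix(0, 3, k)
  votes[2, 1] <- 1
  votes[3, 2] <- 1
  structure(list(var = c(as.integer(v), 0L, 0L), thr = c(thr, 0, 0),
                 cmask = integer(3), left = c(2L, 0L, 0L),
                 right = c(3L, 0L, 0L), n = c(2L, 1L, 1L), votes = votes),
            class = "rf_tree")
}

stub_forest <- function(trees, names, is_cat = rep(FALSE, length(names)),
                        levels = vector("list", length(names)), k = 2) {
  structure(list(trees = trees,
                 bags = rep(list(integer(0)), length(trees)),
                 params = forest_params(ntree = length(trees)),
                 schema = list(names = names, is_cat = is_cat,
                               levels = levels),
                 classes = seq_len(k), n_records = 0L),
            class = "rf_forest")
}
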