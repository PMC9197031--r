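# Synthetic survey bundles: environmental gradients fitted to published
# marginal quantiles, Gaussian-copula dependence, substrate coupled to a
# latent river-size axis, and group-structured species occupancy driven by
# logistic niche thresholds.  Every draw is seeded; one master seed fans
# out to per-stage child seeds.

# Table of marginal quantile targets (q5, q50, q95) per continuous
# variable and per-variable MCAR missingness fractions used as defaults.
.DEFAULT_QUANTILES <- list(
  alkalinity       = c(q5 = 0.4,  q50 = 2.6,  q95 = 6.6),
  velocity         = c(q5 = 0.10, q50 = 0.50, q95 = 0.80),
  nitrate          = c(q5 = 0.11, q50 = 2.51, q95 = 17.0),
  total_phosphorus = c(q5 = 19,   q50 = 110,  q95 = 796),
  width            = c(q5 = 2,    q50 = 8,    q95 = 82),
  depth            = c(q5 = 0.1,  q50 = 0.4,  q95 = 1.5)
)

.DEFAULT_MISSING <- c(alkalinity = 0.52, velocity = 0.60, nitrate = 0.17,
                      total_phosphorus = 0.35, width = 0.14, depth = 0.28,
                      substrate = 54 / 1896)

# Marginal substrate frequencies among observed sites (counts
# 662/339/279/255/219/54/34), in SUBSTRATE_LEVELS order.
.SUBSTRATE_PROBS <- c(662, 339, 279, 255, 219, 54, 34) / 1842

# Categories ranked coarse -> fine; the latent river-size axis pushes
# wider/deeper sites toward the fine end.
.SUBSTRATE_COARSE_TO_FINE <- c("Rock and gravel", "Gravel and boulder",
                               "Gravel", "Sand and gravel",
                               "Silt, sand and gravel", "Sand",
                               "Silt and sand")

#' Fit a lognormal distribution to three quantile targets
#'
#' Two parameters cannot match three quantiles in general, so the median is
#' matched exactly (`meanlog = log(q50)`) and the log-scale spread is the
#' least-squares solution for the 5% and 95% targets, which has the closed
#' form `sdlog = (log(q95) - log(q5)) / (2 z)` with `z` the standard normal
#' 95% quantile.  When `q5 * q95 = q50^2` (log-symmetric targets) all three
#' quantiles are matched exactly.
#'
#' @param q5,q50,q95 Target quantiles, `0 < q5 < q50 < q95`, in the
#'   variable's units.
#' @return List with `meanlog`, `sdlog` and `achieved` (the fitted 5/50/95%
#'   quantiles, for reporting).
#' @export
fit_positive_distribution <- function(q5, q50, q95) {
  if (!(is.finite(q5) && is.finite(q50) && is.finite(q95)))
    stop("quantile targets must be finite")
  if (!(q5 > 0 && q5 < q50 && q50 < q95))
    stop("quantile targets must satisfy 0 < q5 < q50 < q95")
  z <- stats::qnorm(0.95)
  meanlog <- log(q50)
  sdlog <- (log(q95) - log(q5)) / (2 * z)
  achieved <- stats::qlnorm(c(0.05, 0.5, 0.95), meanlog, sdlog)
  names(achieved) <- c("q5", "q50", "q95")
  structure(list(meanlog = meanlog, sdlog = sdlog, achieved = achieved),
            class = "lognormal_fit")
}

#' Gradient specification for the site generator
#'
#' Bundles the marginal quantile targets, the Gaussian-copula correlation
#' matrix among the six continuous gradients, per-variable missingness
#' fractions, and the strength of the substrate--river-size link.
#'
#' Defaults reproduce the published survey template: marginal 5/50/95%
#' quantiles and missingness fractions of the monitoring dataset, plus a
#' moderate dependence structure (alkalinity--nitrate--phosphorus
#' positively associated, width--depth correlation 0.7) chosen as
#' ecologically plausible; the source data report no between-variable
#' correlations, so these are free parameters of the generator, not
#' estimates.
#'
#' @param quantiles Named list of `c(q5, q50, q95)` per continuous variable.
#' @param correlations 6x6 symmetric positive-definite copula correlation
#'   matrix (dimnames = variables).
#' @param missing Named missingness fractions in `[0, 1)`, including
#'   `substrate`.
#' @param substrate_size_link Correlation in `[0, 1)` between the latent
#'   river-size axis (standardised mean of the width and depth copula
#'   scores) and the latent ordinal substrate score; larger values couple
#'   finer substrate more tightly to larger rivers.
#' @return A `gradient_spec` list.
#' @export
gradient_spec <- function(quantiles = .DEFAULT_QUANTILES,
                          correlations = default_copula_correlations(),
                          missing = .DEFAULT_MISSING,
                          substrate_size_link = 0.6) {
  stopifnot(all(ENV_VARS %in% names(quantiles)))
  for (v in ENV_VARS) {
    q <- quantiles[[v]]
    if (!(q[1] > 0 && q[1] < q[2] && q[2] < q[3]))
      stop("quantiles for '", v, "' must be increasing and positive")
  }
  correlations <- as.matrix(correlations)
  if (!all(dim(correlations) == c(6, 6)))
    stop("copula correlation matrix must be 6 x 6")
  if (is.null(dimnames(correlations)))
    dimnames(correlations) <- list(ENV_VARS, ENV_VARS)
  if (!isSymmetric(unname(correlations)))
    stop("copula correlation matrix must be symmetric")
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("copula correlation matrix must be positive-definite")
  if (any(missing < 0 | missing >= 1))
    stop("missing fractions must lie in [0, 1)")
  stopifnot(substrate_size_link >= 0, substrate_size_link < 1)
  structure(list(quantiles = quantiles[ENV_VARS],
                 fits = lapply(quantiles[ENV_VARS], function(q)
                   fit_positive_distribution(q[1], q[2], q[3])),
                 correlations = correlations,
                 missing = missing,
                 substrate_size_link = substrate_size_link),
            class = "gradient_spec")
}

#' Default copula correlation matrix
#'
#' Nutrient/alkalinity gradients mildly associated, width and depth
#' strongly associated (a river-size axis), velocity independent.
#'
#' @return 6x6 correlation matrix over [env_variables()].
#' @export
default_copula_correlations <- function() {
  R <- diag(6)
  dimnames(R) <- list(ENV_VARS, ENV_VARS)
  set_cor <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_cor("alkalinity", "nitrate", 0.4)
  set_cor("alkalinity", "total_phosphorus", 0.3)
  set_cor("nitrate", "total_phosphorus", 0.5)
  set_cor("width", "depth", 0.7)
  R
}

#' Generate a complete synthetic site table
#'
#' Draws the six continuous predictors from a Gaussian copula with the
#' spec's correlation matrix, mapped through the fitted lognormal
#' marginals.  Substrate is sampled by an ordered-probit rule: a latent
#' score correlated with the standardised river-size axis (mean of the
#' width and depth copula scores) is cut at thresholds chosen so the
#' marginal category frequencies match the published substrate counts,
#' with categories ordered coarse to fine so that wider/deeper sites
#' receive finer substrate.
#'
#' @param spec A [gradient_spec()].
#' @param n_sites Number of sites (>= 10).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A complete `site_table` (no missing cells).
#' @export
generate_sites <- function(spec, n_sites, seed) {
  stopifnot(inherits(spec, "gradient_spec"), n_sites >= 10)
  set.seed(seed)
  L <- chol(spec$correlations)
  Z <- matrix(stats::rnorm(n_sites * 6), n_sites, 6) %*% L
  colnames(Z) <- ENV_VARS
  df <- data.frame(site_id = sprintf("S%05d", seq_len(n_sites)))
  for (v in ENV_VARS) {
    fit <- spec$fits[[v]]
    df[[v]] <- stats::qlnorm(stats::pnorm(Z[, v]), fit$meanlog, fit$sdlog)
  }
  size <- (Z[, "width"] + Z[, "depth"])
  size <- size / sqrt(2 + 2 * spec$correlations["width", "depth"])
  rho <- spec$substrate_size_link
  u <- rho * size + sqrt(1 - rho^2) * stats::rnorm(n_sites)
  p_fine_order <- .SUBSTRATE_PROBS[match(.SUBSTRATE_COARSE_TO_FINE,
                                         SUBSTRATE_LEVELS)]
  cuts <- stats::qnorm(cumsum(p_fine_order))
  cuts[length(cuts)] <- Inf
  df$substrate <- .SUBSTRATE_COARSE_TO_FINE[findInterval(u, cuts) + 1L]
  as_site_table(df)
}

#' Specify one group's environmental niche
#'
#' A niche is a set of soft thresholds on continuous gradients plus a
#' substrate preference.  Occupancy probability of a species of this group
#' at a site is
#' `baseline * prod(logistic terms) * (7 * substrate weight)`, clipped to
#' `[0, 1]`.  Each logistic term is `1 / (1 + exp(±(x - threshold) /
#' softness))` with the sign set by `direction`; `softness = 0` gives a
#' hard step.  Substrate weights are stored summing to 1 and applied
#' normalised to mean 1, so a uniform preference is occupancy-neutral and
#' `baseline` is the occupancy at the threshold-favoured end of every
#' gradient under uniform substrate preference.
#'
#' @param group_id Integer group label.
#' @param vars Named list; each element `list(direction = "above"|"below",
#'   threshold = <units>, softness = <units >= 0>)`.
#' @param substrate_weights Numeric length-7 vector (order of
#'   [substrate_levels()]), non-negative, summing to 1.  Default uniform.
#' @param baseline Baseline occupancy probability in (0, 1).
#' @return A `niche_spec` list.
#' @export
niche_spec <- function(group_id, vars = list(),
                       substrate_weights = rep(1 / 7, 7), baseline = 0.3) {
  stopifnot(length(substrate_weights) == 7, all(substrate_weights >= 0))
  if (abs(sum(substrate_weights) - 1) > 1e-8)
    stop("substrate weights must sum to 1")
  stopifnot(baseline > 0, baseline < 1)
  for (v in names(vars)) {
    stopifnot(v %in% ENV_VARS)
    stopifnot(vars[[v]]$direction %in% c("above", "below"),
              vars[[v]]$softness >= 0, vars[[v]]$threshold > 0)
  }
  structure(list(group_id = as.integer(group_id), vars = vars,
                 substrate_weights = stats::setNames(substrate_weights,
                                                     SUBSTRATE_LEVELS),
                 baseline = baseline),
            class = "niche_spec")
}

# Logistic occupancy term for one niche variable.
.niche_term <- function(x, direction, threshold, softness) {
  d <- if (direction == "below") x - threshold else threshold - x
  if (softness == 0) as.numeric(d < 0) else 1 / (1 + exp(d / softness))
}

# Per-site occupancy probability for one niche.
.occupancy <- function(sites, niche) {
  p <- rep(niche$baseline, nrow(sites))
  for (v in names(niche$vars)) {
    nv <- niche$vars[[v]]
    p <- p * .niche_term(sites[[v]], nv$direction, nv$threshold, nv$softness)
  }
  w <- niche$substrate_weights[as.integer(sites$substrate)] * 7
  pmin(p * w, 1)
}

#' Default planted niches (four groups)
#'
#' Mirrors the qualitative ecology of the four recurrent macrophyte
#' groups: (1) mosses of fast, soft-water, low-phosphorus upland brooks on
#' coarse substrate; (2) short pioneer species of shallow low-phosphorus
#' streams; (3) emergent/floating species of slow, deep, alkaline lowland
#' rivers on fine substrate; (4) eutraphent species of wide, deep,
#' phosphorus-rich rivers on fine substrate.  The phosphorus threshold is
#' planted at 130 ug L-1, inside the discriminative range the method
#' should recover.
#'
#' The niche softness values are deliberately broad (the gradients overlap
#' heavily, as in real surveys), which places the out-of-bag kappa of the
#' 4-group model in the fair-agreement band and makes the kappa-threshold
#' selection of the group count a meaningful test rather than a foregone
#' conclusion.
#'
#' @param tp_threshold Total-phosphorus threshold (ug L-1) shared by the
#'   phosphorus-responsive groups.
#' @return List of four [niche_spec()] objects.
#' @export
default_niches <- function(tp_threshold = 130) {
  w_coarse <- c(0.08, 0.06, 0.26, 0.22, 0.05, 0.12, 0.21)
  w_mid    <- c(0.16, 0.16, 0.14, 0.22, 0.10, 0.16, 0.06)
  w_fine   <- c(0.28, 0.24, 0.05, 0.08, 0.26, 0.05, 0.04)
  list(
    niche_spec(1L, list(
      velocity = list(direction = "above", threshold = 0.40, softness = 0.12),
      total_phosphorus = list(direction = "below", threshold = tp_threshold,
                              softness = 60)),
      substrate_weights = w_coarse, baseline = 0.80),
    niche_spec(2L, list(
      depth = list(direction = "below", threshold = 0.45, softness = 0.15),
      total_phosphorus = list(direction = "below", threshold = tp_threshold,
                              softness = 60)),
      substrate_weights = w_mid, baseline = 0.70),
    niche_spec(3L, list(
      velocity = list(direction = "below", threshold = 0.40, softness = 0.12),
      depth = list(direction = "above", threshold = 0.40, softness = 0.15),
      alkalinity = list(direction = "above", threshold = 2.0, softness = 0.8)),
      substrate_weights = w_fine, baseline = 0.75),
    niche_spec(4L, list(
      total_phosphorus = list(direction = "above", threshold = tp_threshold,
                              softness = 60),
      width = list(direction = "above", threshold = 15, softness = 8)),
      substrate_weights = w_fine, baseline = 0.80)
  )
}

#' Generate species occurrences with planted group structure
#'
#' Species are assigned round-robin to the niche groups; presence of each
#' species at each site is an independent Bernoulli draw with the group's
#' occupancy probability (see [niche_spec()]).
#'
#' @param sites A complete `site_table`.
#' @param niches List of [niche_spec()] objects, one per group.
#' @param n_species Number of species (>= number of groups).
#' @param seed Integer seed.
#' @return List with `occurrences` (an `occurrence_table`, all species
#'   flagged aquatic) and `truth` (a `truth_bundle`: `species_group`,
#'   `niches` and the planted `thresholds` per variable).
#' @export
generate_occurrences <- function(sites, niches, n_species, seed) {
  G <- length(niches)
  stopifnot(n_species >= G)
  set.seed(seed)
  species <- sprintf("sp%03d", seq_len(n_species))
  group <- stats::setNames(rep(seq_len(G), length.out = n_species), species)
  P <- vapply(niches, function(nc) .occupancy(sites, nc),
              numeric(nrow(sites)))
  expected <- colSums(P)[group]
  if (any(expected < 1))
    stop("expected occurrences per species < 1 for some species; ",
         "increase baseline occupancy or n_sites")
  recs <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    hit <- stats::runif(nrow(sites)) < P[, group[s]]
    if (any(hit))
      recs[[s]] <- data.frame(site_id = sites$site_id[hit],
                              species_id = species[s], aquatic = TRUE)
  }
  occ <- as_occurrence_table(do.call(rbind, recs))
  thresholds <- list()
  for (nc in niches)
    for (v in names(nc$vars))
      thresholds[[v]] <- sort(unique(c(thresholds[[v]],
                                       nc$vars[[v]]$threshold)))
  truth <- structure(list(species_group = group, niches = niches,
                          thresholds = thresholds),
                     class = "truth_bundle")
  list(occurrences = occ, truth = truth)
}

#' Mask site-table cells completely at random
#'
#' Each cell of each variable is masked independently with that variable's
#' fraction (MCAR), emulating the missingness pattern of heterogeneous
#' monitoring programmes.
#'
#' @param sites A `site_table`.
#' @param fractions Named fractions in `[0, 1)` per variable (may include
#'   `substrate`); defaults to the published missingness pattern.
#' @param seed Integer seed.
#' @return The `site_table` with masked cells set to `NA`.
#' @export
apply_missingness <- function(sites, fractions = .DEFAULT_MISSING, seed) {
  stopifnot(all(fractions >= 0 & fractions < 1))
  set.seed(seed)
  for (v in intersect(names(fractions), c(ENV_VARS, "substrate"))) {
    if (fractions[[v]] == 0) next
    mask <- stats::runif(nrow(sites)) < fractions[[v]]
    sites[[v]][mask] <- NA
  }
  sites
}

#' Simulate a complete survey bundle
#'
#' One master seed fans out to child seeds for site generation, occurrence
#' generation and missingness, so each stage is reproducible in isolation.
#' The default desk-scale configuration (400 sites, 24 species, 4 niche
#' groups) keeps the full pipeline testable in minutes; pass the published
#' survey dimensions (1896 sites, 62 species) for a full-scale bundle.
#'
#' @param n_sites,n_species Survey dimensions.
#' @param spec A [gradient_spec()].
#' @param niches List of [niche_spec()]; defaults to [default_niches()].
#' @param seed Master integer seed.
#' @param missing If `TRUE` (default) apply the spec's missingness
#'   fractions to the returned `sites`.
#' @return List with `sites_complete` (no missing cells), `sites` (with
#'   missingness applied), `occurrences`, `truth` and the child `seeds`.
#' @export
simulate_survey <- function(n_sites = 400, n_species = 24,
                            spec = gradient_spec(),
                            niches = default_niches(), seed = 1,
                            missing = TRUE) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 3)
  sites_complete <- generate_sites(spec, n_sites, child[1])
  go <- generate_occurrences(sites_complete, niches, n_species, child[2])
  sites <- if (missing)
    apply_missingness(sites_complete, spec$missing, child[3])
  else sites_complete
  list(sites_complete = sites_complete, sites = sites,
       occurrences = go$occurrences, truth = go$truth,
       seeds = c(sites = child[1], occurrences = child[2],
                 missingness = child[3]))
}

#' Write a survey bundle to disk
#'
#' Writes `sites.csv`, `occurrences.csv` and `truth.json` into `dir`.
#'
#' @param bundle Result of [simulate_survey()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_site_table(bundle$sites, file.path(dir, "sites.csv"))
  write_occurrences(bundle$occurrences, file.path(dir, "occurrences.csv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(species_group = as.list(truth$species_group),
         thresholds = truth$thresholds,
         niches = lapply(truth$niches, unclass)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
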