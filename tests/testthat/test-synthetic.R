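test_that("lognormal quantile fit matches its targets", {
  # median matched exactly for the width-like targets
  f <- fit_positive_distribution(2, 8, 82)
  expect_equal(unname(f$achieved["q50"]), 8)
  expect_equal(exp(f$meanlog), 8)

  # log-symmetric targets are matched exactly at all three points
  f2 <- fit_positive_distribution(1, 10, 100)
  expect_equal(unname(f2$achieved), c(1, 10, 100), tolerance = 1e-10)

  expect_error(fit_positive_distribution(5, 2, 10), "q5 < q50")
  expect_error(fit_positive_distribution(0, 2, 10), "q5 < q50")
})

test_that("sampling the depth fit reproduces its achieved quantiles", {
  f <- fit_positive_distribution(0.1, 0.4, 1.5)
  set.seed(99)
  draws <- stats::rlnorm(1e5, f$meanlog, f$sdlog)
  emp <- stats::quantile(draws, c(0.05, 0.5, 0.95), names = FALSE)
  expect_equal(emp, unname(f$achieved), tolerance = 0.05)
})

test_that("gradient spec validates its inputs", {
  expect_error(gradient_spec(missing = c(alkalinity = 1.0)), "\\[0, 1\\)")
  bad <- default_copula_correlations()
  bad[1, 2] <- 0.9  # asymmetric
  expect_error(gradient_spec(correlations = bad), "symmetric")
  bad2 <- matrix(0.99, 6, 6)
  diag(bad2) <- 1
  bad2[1, 2] <- bad2[2, 1] <- -0.99
  expect_error(gradient_spec(correlations = bad2), "positive-definite")
})

test_that("generated sites follow the copula correlation structure", {
  # independence
  sp0 <- gradient_spec(correlations = diag(6) + 0)
  s0 <- generate_sites(sp0, 200, seed = 4)
  combos <- utils::combn(env_variables(), 2)
  rho <- apply(combos, 2, function(p)
    stats::cor(s0[[p[1]]], s0[[p[2]]], method = "spearman"))
  expect_true(all(abs(rho) < 0.15))

  # planted width-depth dependence
  s1 <- generate_sites(gradient_spec(), 2000, seed = 4)
  expect_equal(stats::cor(s1$width, s1$depth, method = "spearman"), 0.7,
               tolerance = 0.1 / 0.7)

  # determinism
  s2 <- generate_sites(gradient_spec(), 200, seed = 4)
  s3 <- generate_sites(gradient_spec(), 200, seed = 4)
  expect_identical(s2, s3)
})

test_that("generated marginals approach the fitted quantile targets", {
  s <- generate_sites(gradient_spec(), 4000, seed = 8)
  for (v in c("alkalinity", "width", "depth")) {
    q <- gradient_spec()$quantiles[[v]]
    emp <- stats::quantile(s[[v]], c(0.05, 0.5, 0.95), names = FALSE)
    ach <- fit_positive_distribution(q[1], q[2], q[3])$achieved
    expect_equal(emp, unname(ach), tolerance = 0.1)
  }
})

test_that("wider and deeper sites carry finer substrate", {
  s <- generate_sites(gradient_spec(), 3000, seed = 9)
  fine <- s$substrate %in% c("Sand", "Silt and sand",
                             "Silt, sand and gravel")
  expect_gt(median(s$width[fine]), median(s$width[!fine]))
  expect_gt(median(s$depth[fine]), median(s$depth[!fine]))
})

test_that("step niches are hard occupancy limits", {
  b <- simulate_survey(300, 8, niches = step_niches(130), seed = 17,
                       missing = FALSE)
  tp <- stats::setNames(b$sites_complete$total_phosphorus,
                        b$sites_complete$site_id)
  below_species <- names(b$truth$species_group)[b$truth$species_group == 1]
  recs <- b$occurrences[b$occurrences$species_id %in% below_species, ]
  expect_true(all(tp[recs$site_id] <= 130))
})

test_that("record totals match the analytic Bernoulli expectation", {
  niches <- lapply(1:4, function(g) niche_spec(g, list(), baseline = 0.1))
  sites <- generate_sites(gradient_spec(), 400, seed = 3)
  go <- generate_occurrences(sites, niches, 24, seed = 5)
  # uniform substrate weights and no niche terms: p = baseline everywhere
  expected <- 24 * 400 * 0.1
  sd_bin <- sqrt(24 * 400 * 0.1 * 0.9)
  expect_lt(abs(nrow(go$occurrences) - expected), 3 * sd_bin)
})

test_that("occurrence generation rejects hopeless configurations", {
  niches <- list(niche_spec(1L, list(), baseline = 0.001),
                 niche_spec(2L, list(), baseline = 0.001))
  sites <- generate_sites(gradient_spec(), 200, seed = 3)
  expect_error(generate_occurrences(sites, niches, 4, seed = 5),
               "expected occurrences")
})

test_that("missingness masking is MCAR with the requested rates", {
  sites <- generate_sites(gradient_spec(), 1000, seed = 6)

  # zero fractions leave the table untouched
  same <- apply_missingness(sites, c(alkalinity = 0), seed = 7)
  expect_identical(as.data.frame(same), as.data.frame(sites))

  masked <- apply_missingness(sites, c(alkalinity = 0.52), seed = 7)
  n_miss <- sum(is.na(masked$alkalinity))
  expect_lt(abs(n_miss - 520), 3 * sqrt(1000 * 0.52 * 0.48))

  # masking independent of the cell value
  m <- is.na(masked$alkalinity)
  x <- sites$alkalinity
  se <- sqrt(stats::var(x[m]) / sum(m) + stats::var(x[!m]) / sum(!m))
  expect_lt(abs(mean(x[m]) - mean(x[!m])), 3 * se)
})

test_that("survey bundles are deterministic and serialize losslessly", {
  b1 <- simulate_survey(100, 8, seed = 42)
  b2 <- simulate_survey(100, 8, seed = 42)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))

  dir <- withr::local_tempdir()
  write_survey(b1, dir)
  expect_true(all(file.exists(file.path(dir, c("sites.csv",
                                               "occurrences.csv",
                                               "truth.json")))))
  back <- read_site_table(file.path(dir, "sites.csv"))
  expect_equal(as.data.frame(back), as.data.frame(b1$sites))
})

test_that("planted step-niche groups are exactly recoverable by clustering", {
  # hard niches, no noise beyond Bernoulli sampling: clustering at the true
  # k recovers the planted partition
  niches <- list(
    niche_spec(1L, list(total_phosphorus = list(direction = "below",
                                                threshold = 110,
                                                softness = 0)),
               baseline = 0.7),
    niche_spec(2L, list(total_phosphorus = list(direction = "above",
                                                threshold = 110,
                                                softness = 0)),
               baseline = 0.7))
  b <- simulate_survey(500, 10, niches = niches, seed = 13,
                       missing = FALSE)
  pm <- build_presence_matrix(b$occurrences, min_sites = 10)
  cl <- cut_dendrogram(ward_linkage(jaccard_distances(pm)), 2)
  expect_equal(rand_index(cl, b$truth$species_group[names(cl)]), 1)
})
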