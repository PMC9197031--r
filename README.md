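# macroranges

Co-occurrence groups of river macrophytes and the environmental ranges
that discriminate between them.

## The problem

River macrophytes (aquatic mosses and vascular plants) form recurrent
groups of species that tend to occur together, and field ecologists have
long described the conditions separating those groups in qualitative terms
("shallow", "nutrient-rich", "fast-flowing"). `macroranges` implements a
pipeline that turns presence/absence survey data plus six continuous
environmental predictors (alkalinity, flow velocity, nitrate, total
phosphorus, width, depth) and a 7-category dominant-substrate variable
into quantitative **discriminative ranges**: the gradient intervals where
a classification model actually separates the species groups.

The pipeline has three stages:

1. **Grouping.** Species recorded at ≥ 25 sites are clustered on their
   co-occurrence pattern: binary Jaccard distance
   *d(a,b) = 1 − |A∩B| / |A∪B|* between presence profiles, agglomerated
   with Ward's criterion applied to the unsquared distances (`ward.D`),
   and cut into *k* = 2, 3, … groups.
2. **Group-count selection.** For each *k*, a random forest predicts the
   group label of every species occurrence from the site's seven
   environmental predictors. Each tree is grown on a class-balanced bag
   (every class undersampled to the minority class count), with a single
   random candidate predictor per node (`mtry = 1`) and a minimum
   terminal node size (`nodesize = 200` at full scale). The scan stops at
   the first *k* whose out-of-bag Cohen's kappa
   *κ = (p₀ − pₑ)/(1 − pₑ)* drops below 0.3; the selected group count is
   the *k* just before the drop.
3. **Discriminative ranges.** With `mtry = 1`, each of the 7 predictors
   occupies the root node of ~1/7 of the trees. For every continuous
   predictor, the minimum, mean and maximum of its root-node split
   thresholds across the forest define its discriminative range — the
   gradient region where the groups are most separable. Partial
   dependence curves of the per-group voting fractions and a
   most-likely-group table for the categorical substrate complete the
   picture.

Incomplete environmental tables are handled by two parallel imputation
tracks — column median/mode substitution, and an iterative forest-based
imputer (missForest-style: initialise, cycle over variables in increasing
missingness order, stop when the out-of-sample change statistic first
increases) — so the sensitivity of the ranges to the imputation choice is
visible rather than hidden.

Because real monitoring compilations of this kind are rarely
redistributable, the package ships a synthetic survey generator:
lognormal marginals fitted to published 5/50/95% quantiles, a Gaussian
copula for between-gradient dependence, substrate coupled to a latent
river-size axis, and species occupancy driven by planted logistic niche
thresholds. The generator's ground truth (true groups, planted
thresholds) is what the test suite recovers.

## Worked example

```r
library(macroranges)

bundle <- simulate_survey(n_sites = 400, n_species = 24, seed = 11)
pm     <- build_presence_matrix(bundle$occurrences, min_sites = 25)
sites  <- impute_median_mode(bundle$sites)$sites

sel <- select_n_groups(pm, sites,
                       forest_params(ntree = 300, mtry = 1,
                                     nodesize = 200, seed = 3),
                       k_max = 8, seed = 5)
sel
#>  k oob_accuracy oob_kappa                  band
#>  2    0.8017241 0.6028853 substantial agreement
#>  3    0.6571618 0.4346826    moderate agreement
#>  4    0.5112732 0.3454514        fair agreement
#>  5    0.4456233 0.2681248        fair agreement
#> selected k: 4 -- kappa dropped below 0.30 at k = 5
```

The generator planted four niche groups; the kappa-threshold rule selects
exactly `k = 4` (the scan stops at the first drop below 0.3). Training
the final forest and extracting the ranges:

```r
assignment <- cut_dendrogram(ward_linkage(jaccard_distances(pm)),
                             sel$selected_k)
ds     <- build_model_dataset(pm, sites, assignment)
forest <- train_forest(ds, forest_params(ntree = 2000, mtry = 1,
                                         nodesize = 200, seed = 3))
discriminative_ranges(forest)
#>           variable count     min    mean     max
#> 1       alkalinity   295   1.612   2.160   4.281
#> 2         velocity   305   0.333   0.362   0.426
#> 3          nitrate   268   0.559   2.567   9.092
#> 4 total_phosphorus   263 114.220 151.429 211.886
#> 5            width   289   2.938  12.149  17.937
#> 6            depth   288   0.252   0.435   0.730
```

Every planted threshold falls inside its recovered range: total
phosphorus was planted at 130 µg L⁻¹ (range 114–212), velocity at
0.40 m s⁻¹ (0.33–0.43), depth at 0.40–0.45 m (0.25–0.73), alkalinity at
2.0 meq L⁻¹ (1.6–4.3). The `count` column confirms that with `mtry = 1`
each predictor roots roughly 2000/7 ≈ 286 trees. The substrate table
shows the planted preference of group 1 for coarse substrate:

```r
substrate_top_group(forest, ds)
#>                category top_group vote_fraction   tie
#> 1 Silt, sand and gravel         3          0.27 FALSE
#> 2                  Sand         4          0.27 FALSE
#> 3    Gravel and boulder         1          0.33 FALSE
#> ...
```

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the whole
workflow (both imputation tracks, selection, holdout check, 10-fold CV,
ranges, PDP curves, substrate table) and writes every stage artifact plus
a JSON-lines log to `out/`.

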