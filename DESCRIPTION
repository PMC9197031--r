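Package: macroranges
Title: Co-Occurrence Groups and Discriminative Environmental Ranges for
    River Macrophytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives groups of co-occurring river macrophyte species from
    presence-absence survey data (Jaccard distance, Ward agglomeration),
    selects the number of groups with an out-of-bag Cohen's kappa
    threshold, and quantifies the environmental ranges that discriminate
    between groups as the spread of root-node split-points in a
    class-undersampled random forest.  Includes median and iterative
    forest-based imputation of incomplete environmental predictors,
    partial dependence of class voting fractions, and a synthetic survey
    generator with planted niche thresholds for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    ggplot2
Config/testthat/edition: 3
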