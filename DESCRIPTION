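Package: vitellus
Title: Follicle Size Hierarchies and Reproductive Energy Budgets for Nesting Sea Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of ovarian follicle censuses from nesting
    sea turtles. Detects bimodality in follicle diameter distributions
    (Hartigan's dip statistic with a Monte-Carlo p-value), selects and fits
    exact one-dimensional k-means partitions to derive the dominant/non-dominant
    diameter threshold, converts ovulatory-scar and dominant-follicle counts
    into clutches laid and left and a clutch-frequency estimate, and builds
    per-female yolk dry-mass, nutrient and energy budgets (investment,
    remaining deposition and resorbable reserve) from a diameter-to-dry-mass
    regression. Includes rank-based block-design comparisons of yolk
    composition across follicle types (Durbin test with pairwise follow-ups)
    and a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
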