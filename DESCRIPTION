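Package: scnet
Title: Structural Covariance Network Analysis of Regional Grey-Matter Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group-level structural covariance network analysis for regional
    grey-matter volume tables. Builds Pearson correlation networks per group
    after residualizing age and sex, thresholds them over a density grid into
    binary graphs, and characterizes them with graph-theoretic measures
    (clustering coefficient, characteristic path length, small-world index
    against degree-preserving random references, nodal betweenness, and
    hub detection at two standard deviations above the mean betweenness).
    Group differences are assessed by subject-relabeling permutation tests
    summarized as areas under the metric-difference curve across densities,
    with Benjamini-Hochberg false discovery rate correction over regions.
    Includes a synthetic cohort generator with block covariance structure,
    confound effects and paired longitudinal measurements, and the
    demographic summary statistics (two-sample t tests from summaries,
    chi-squared tests, repeated-measures ANOVA) used to describe such
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
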