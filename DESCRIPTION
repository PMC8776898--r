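Package: covmorph
Title: Regional Brain Morphometry and Structural Covariance Analysis for
    Mouse MRI Cohorts
Version: 0.1.0
Authors@R:
    person("covmorph", "developers", email = "covmorph@example.org",
           role = c("aut", "cre"))
Description: Tools for atlas-based regional volumetric analysis of mouse
    brain MRI cohorts with a two-by-two (sex by treatment) design: total and
    regional volume group comparisons with false-discovery-rate control
    (Benjamini-Hochberg and the Benjamini-Krieger-Yekutieli two-stage
    step-up procedure) and Cohen's d effect sizes, tests for loss of sexual
    dimorphism in a-priori regions, cluster-averaged structural covariance
    comparison across groups using Kruskal-Wallis tests with eta-squared
    large-effect filtering, and sex-stratified brain-behavior Pearson
    correlation maps ordered by average-linkage hierarchical clustering.
    Includes a synthetic cohort generator with block-structured covariance
    and a ground-truth record, minimal NIfTI-1 label-image input/output for
    voxel-count volume extraction, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
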