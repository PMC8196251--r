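Package: svdstrat
Title: Stratification and Neuroanatomic Analysis of Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R:
    person("SVD", "Pipeline Maintainers", email = "maintainers@svdstrat.dev",
           role = c("aut", "cre"))
Description: Rule-based stratification of older adults into cerebral
    small-vessel-disease (SVD) subtypes from MRI marker tables (white-matter
    hyperintensity burden, lacunes, cerebral microbleed topography), composite
    physical-frailty and cognitive-impairment scoring, nonparametric and
    regression group statistics, permutation-based voxel-wise ANCOVA with
    cluster-level family-wise-error inference (including ordered trend
    contrasts), hierarchical clustering of statistical-map spatial patterns
    with Calinski-Harabasz model selection, and regional distribution
    summaries.  A synthetic-cohort module generates subject tables and 3D
    image sets with the statistical structure the analysis assumes, so the
    whole pipeline is testable without access to a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
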