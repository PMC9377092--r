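Package: qpopr
Title: Quadratic Optimization of Drug Combinations from Orthogonal Array Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for small-sample drug-combination
    optimization in tumor organoid cohorts. Builds orthogonal array composite
    designs (a three-level L27 orthogonal array concatenated with a two-level
    regular fractional factorial) for combinatorial dosing, fits second-order
    quadratic response surfaces to a tumor-versus-normal therapeutic output,
    ranks all two-drug combinations with cohort-level frequency analysis and
    rank-profile clustering, and validates candidate pairs with Chou-Talalay
    combination-index and dose-reduction-index profiles from median-effect
    dose-response fits. Includes a ground-truth viability simulator (Hill
    single-drug kill, Bliss composition, planted pairwise interactions) so the
    whole pipeline can be exercised and tested without experimental data, plus
    screening-arm statistics (median-viability hit calling, tumor volume and
    growth rate, pathway-score correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
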