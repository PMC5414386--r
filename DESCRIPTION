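Package: emoturn
Title: Turning-Point Analysis of Intra-Individual Emotion Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects turning points in short intra-individual emotion
    trajectories measured on Likert scales. Each trajectory is screened
    for exceptional points falling outside a residual control band of
    1.65 standard deviations around its ordinary least-squares trend;
    exceptional points are promoted to turning points when a Monte Carlo
    permutation test finds a significant change between the pre- and
    post-point segment slopes; and a within-participant permutation test
    assesses whether perceived task complexity is elevated at occasions
    where turning points occur. Includes a synthetic-cohort generator
    with ground-truth logs for calibration and recovery studies, and
    report builders for the standard summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
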