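Package: methpower
Title: Simulation-Based Power Estimation for Epigenome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates statistical power for two-group epigenome-wide
    association studies (EWAS) of array-based DNA methylation. CpG-specific
    beta-values are simulated from beta distributions parameterized by a
    tissue-specific reference panel of per-CpG means and variances; group
    differences are injected as feasibility-bounded truncated-normal effect
    sizes with automatic calibration of the effect-size spread to a target
    maximal difference; differential methylation is tested per CpG (moderated
    t, pooled t, Welch t, or Wilcoxon rank-sum) with Benjamini-Hochberg FDR
    control; and marginal power, marginal type I error, empirical FDR and
    false discovery cost are reported across sample-size by effect-size grids
    with Monte-Carlo uncertainty bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
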