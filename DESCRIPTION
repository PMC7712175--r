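Package: balancemdc
Title: Minimal Detectable Change and Magnitude-Based Monitoring for
    Stabilometric Balance Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for posturographic balance assessment with a four-load-cell
    force platform: compute centre-of-pressure (COP) trajectories, extract
    static (Romberg/CTSIB-M) and dynamic limits-of-stability (LOS) sway
    variables, estimate test-retest reliability (intraclass correlation,
    standard error of measurement, minimal detectable change MDC95 and its
    effect size), and classify individual pre/post-treatment change with a
    magnitude-based decision procedure using MDC thresholds.  A synthetic-data
    generator (Ornstein-Uhlenbeck sway, target-directed LOS excursions,
    test-retest cohorts and patient pairs with known ground truth) makes the
    whole pipeline testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
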