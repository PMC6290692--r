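Package: lifedisparity
Title: Lifespan Variation Analysis for Period Mortality Under Crisis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds period life tables from age-specific death rates and
    analyses lifespan variation through life disparity (e-dagger), the
    threshold age, Keyfitz entropy and the life-table Gini coefficient.
    Changes in life expectancy and life disparity are attributed to single
    ages and to age-by-cause-of-death groups with a numerical line-integral
    (Horiuchi) decomposition.  Trend tooling includes penalized smoothing of
    mortality surfaces, annual rates of mortality improvement, divisive
    energy-statistic change-point detection for period segmentation, and a
    paired first-difference quadrant analysis.  A deterministic synthetic
    mortality generator (Siler hazard with a young-adult hump and
    regime-driven crisis multipliers) plus readers and writers for HMD-style
    Mx 1x1 files and cause-of-death tables allow the full pipeline to run
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
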