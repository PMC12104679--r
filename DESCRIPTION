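Package: needledyn
Title: Needle-Angle Dynamics and Image-Based Early Detection of Drought
    Stress in Conifer Seedlings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for early drought-stress detection in
    conifer seedlings from time-lapse side-view imagery. Provides a seeded
    synthetic-experiment generator (scenes with a colour chart, thermal
    maps, environment and physiology tables, ground truth), chart-based
    colour correction and mask segmentation, the eleven seedling-level
    morphometric parameters (area, convex hull, solidity, perimeter,
    centre of mass, longest path, fitted-ellipse centre and extents),
    apical needle-angle parameters (quadrant-averaged theta, STx bins,
    BD-M, PM-M, PM-M(ST)) with vitality bookkeeping, thermal stress
    indices (Tetens vapour pressures, VPD, two CWSI variants, LTD), a
    statistical battery (mixed repeated-measures ANOVA, Bonferroni
    pairwise t tests with compact letter displays, Kruskal-Wallis plus
    Mann-Whitney, stepwise regression with collinearity and
    autocorrelation diagnostics, PCA), and an orchestrator that reports
    the earliest session at which drought and control diverge for each
    parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
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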