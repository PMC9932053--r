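Package: gaitscale
Title: Multi-Scale Detrended Fluctuation and Partial Cross-Correlation
    Analysis of Body-Part Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-scale analysis of animal locomotor
    trajectories obtained from marker-free video tracking. Reads and
    preprocesses body-part trajectory tables in the DeepLabCut CSV
    dialect, computes detrended fluctuation (DFA), detrended
    cross-correlation (DCCA) and detrended partial cross-correlation
    (DPCCA) matrices over a grid of time scales, localizes scaling
    crossovers of the fluctuation functions, compares metric
    distributions between cohorts with outlier fencing and
    nonparametric tests across scales and gliding time windows, and
    reconstructs directed body-part coupling networks from
    delay-aligned partial correlations. Includes a synthetic-trajectory
    generator with tunable two-regime scaling, inter-part coupling and
    delays, so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
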