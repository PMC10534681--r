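Package: lacriflow
Title: Simulated Tear-Flow Clearance Modelling and Corneal Permeation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling precorneal clearance in dynamic ex vivo
    ocular permeation experiments.  Implements piecewise exponential
    washout of a donor compartment under sequential tear-flow regimes
    (with conversions between per-minute clearance percentages, continuous
    clearance coefficients and peristaltic pump flows), a data model for
    donor-compartment prototype geometry with ratio-based version ranking,
    inverse prediction of drug concentration from an HPLC calibration line
    with LOD/LOQ flagging, a seeded generator of synthetic static- and
    dynamic-arm corneal penetration datasets, and a statistics pipeline
    (one-way ANOVA, Tukey HSD multiple comparisons, static/dynamic
    overestimation ratios) for formulation comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
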