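Package: wbcplt
Title: Kinetics of Acute Inflammatory Recovery from WBC and Platelet Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal white blood cell (WBC) and
    platelet (PLT) dynamics during recovery from acute inflammation
    (surgery, ischemia, infection). Implements the exponential-WBC-decay /
    delayed-linear-PLT-growth recovery model with per-patient nonlinear
    least-squares fitting, non-dimensionalization onto a universal recovery
    shape, construction of a reference mean WBC-PLT phase-plane trajectory
    from favorable recoveries, positional and directional risk scoring of
    patient-days against that reference with out-of-sample percentile
    thresholds, relative-risk and chi-squared stratum analysis, and
    exploratory k-means clustering of high-dimensional marker trajectories.
    Includes a synthetic-cohort generator emulating hospital laboratory
    time series so the full pipeline is testable without access to
    protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
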