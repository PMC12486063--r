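Package: letseek
Title: Simultaneous Proton Dose and LET-Weighted Dose Plan Reoptimization
    via Feasibility-Seeking and Superiorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reoptimizes intensity-modulated proton therapy (IMPT) spot
    weights by simultaneous-projection feasibility-seeking (AMS) over
    per-voxel interval constraints in dose space (targets) and in
    c*dose*LETd space (organs at risk), and by superiorization of that
    iteration with bounded negative-gradient perturbations of a weighted
    least-squares objective. Operates on sparse two-component influence
    matrices (dose and dose-averaged-LET numerator), builds organ-at-risk
    upper bounds from volume-histogram percentiles (cDL30) of a baseline
    forward calculation, and ships an analytic pencil-beam phantom
    simulator so the whole pipeline runs on synthetic data. Includes
    DVH/LVH/cDLVH analytics, a nine-scenario setup and density robustness
    protocol, MetaImage (.mhd/.mha) image I/O, a plain-text sparse
    influence matrix format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
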