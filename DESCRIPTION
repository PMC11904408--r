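Package: surfaceKR
Title: Structured-Output Kernel Regression for Drug Combination Dose-Response Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts full, continuous drug-combination dose-response surfaces for
    (cell line, drug, drug) triplets with input-output kernel regression. Monotherapy
    behaviour is summarised by Hill curves and combination surfaces by the BRAID model;
    surfaces are embedded with a Nystrom-approximated output kernel feature map, the
    ridge-regression system with sampled Kronecker-product structure is solved by an
    early-stopped conjugate-gradient vec-trick solver, and predictions are recovered by
    candidate-set or projected-gradient pre-image optimisation. Includes Bliss and Loewe
    synergy scoring from surfaces, scenario-respecting train/test splits, and a synthetic
    data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
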