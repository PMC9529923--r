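Package: perturbench
Title: Perturbation-Design-Aware Gene Regulatory Network Inference and
    Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, inference and evaluation toolkit for studying how
    much knowledge of the perturbation design matters in gene regulatory
    network (GRN) inference. Generates stable, signed, scale-free in silico
    networks, single-gene knockdown designs and steady-state fold-change
    expression with Gaussian noise calibrated to a target signal-to-noise
    ratio; fits perturbation-design-based estimators (least squares, lasso,
    elastic net, ridge, Z-score) and expression-only estimators (a
    GENIE3-style tree ensemble and a CLR-style mutual-information method)
    through a single modelling interface; and scores predictions against the
    true network with sparsity sweeps, AUPR/AUROC, F1, Matthews correlation,
    selfloop-aware gold-standard handling, and between-method similarity
    analyses. Includes a benchmark driver covering scrambled-design controls
    and a reader for DREAM5-style known-target perturbation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    MASS,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
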