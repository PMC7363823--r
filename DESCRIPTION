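Package: fermsensor
Title: Multi-Output Least-Squares SVM Soft Sensors for Fed-Batch Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Soft-sensor modelling of fed-batch fermentation processes: a
    multi-output least-squares support vector machine (MLSSVM) regressor
    trained by solving a block KKT linear system with an RBF kernel, with its
    three hyperparameters (penalty gamma, output-coupling penalty lambda,
    kernel width sigma) tuned by an improved cuckoo search with adaptive
    discovery probability and Levy-flight step size. Includes standard cuckoo
    search, particle swarm and genetic algorithm baselines, a Monod /
    Luedeking-Piret fed-batch fermentation simulator that emulates the
    sampling design of industrial soft-sensor campaigns (15-min auxiliary
    inputs, 2-h offline assays spline-resampled onto the fine grid),
    leave-one-batch-out cross-validation, and an optimizer comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
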