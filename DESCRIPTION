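Package: mklsvm
Title: Multiple-Kernel SVM Lung Nodule Recognition with Hybrid
    Simulated-Annealing Particle-Swarm Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computer-aided recognition of lung-CT nodule candidates with a
    soft-margin support vector machine whose kernel is a convex combination of
    a polynomial and a sigmoid kernel. The four free hyperparameters (kernel
    mix weight, box constraint, and the two sigmoid parameters) are tuned by a
    hybrid simulated-annealing/particle-swarm optimizer that maximizes a
    5-fold cross-validated harmonic mean of accuracy and sensitivity. Includes
    the feature pipeline (region-of-interest binarization, largest
    8-connected-region reconstruction, 13 handcrafted morphology/intensity/
    texture descriptors, a pluggable image-embedding hook with PCA reduction,
    and cascade concatenation), plain particle-swarm and grid-search
    baselines, confusion-matrix/ROC metrics, synthetic data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    Rcpp,
    grDevices,
    graphics,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
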