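Package: stepcountr
Title: Carrying-Position-Independent Step Counting from Smartphone Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating walking step counts from tri-axial smartphone
    acceleration recordings independently of where the phone is carried
    (handheld, trouser pocket, or handbag). Implements plantar-pressure-based
    automatic step labeling (sensor-range clipping, moving-average smoothing,
    threshold peak detection with a refractory period), sliding-window
    supervised dataset construction, a two-stage ensemble model that first
    classifies the carrying position and then routes each recording to
    position-specific step-count regressors (random forest, linear support
    vector machine, multilayer perceptron, histogram gradient boosting,
    k-nearest neighbours, and their weighted-average ensemble), and step-count
    accuracy evaluation with position-by-algorithm report tables. Includes a
    deterministic synthetic gait simulator that produces paired
    acceleration/pressure recordings with known ground-truth step events for
    testing and benchmarking, plus CSV interchange formats and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    class,
    e1071,
    nnet,
    randomForest,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
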