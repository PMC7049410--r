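Package: decolopt
Title: Response-Surface and Neural-Network Optimization of Microbial Dye
    Decolorization Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing microbial decolorization of the triazo
    textile dye Direct Blue 71 (and similar bounded bioprocess responses)
    from three-factor Box-Behnken experiments. Builds coded/natural
    Box-Behnken design tables, fits the ten-term coded quadratic response
    surface by ordinary least squares with a full Design-Expert style
    ANOVA (partial sums of squares, lack-of-fit versus pure error, PRESS,
    predicted R-squared, adequate precision, studentized-residual
    diagnostics), trains small feedforward neural networks by seeded
    full-batch backpropagation with momentum, locates desirability-based
    optima under per-factor goal policies, exports response-surface grids,
    and compares competing predictors by R-squared and absolute average
    deviation. Includes a generator for synthetic Box-Behnken datasets
    with known quadratic ground truth, the canonical 17-run dye
    decolorization dataset, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
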