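Package: codopt
Title: Statistical and Neural Surrogate Optimization of Fermentation Media
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hybrid statistical/machine-learning workflow for optimizing
    fermentation medium composition, built around cholesterol oxidase
    production data from a five-factor circumscribed central composite
    design. Generates central composite designs, fits full second-order
    response-surface models by ordinary least squares with per-term ANOVA,
    trains small feed-forward neural networks (tansig hidden layer, linear
    output) by gradient descent, adaptive-rate gradient descent or
    Levenberg-Marquardt, and maximizes either fitted surrogate with a
    real-coded genetic algorithm using rank fitness scaling, stochastic
    universal sampling and scattered crossover. Includes a synthetic-data
    generator with known ground truth for end-to-end parameter-recovery
    benchmarking, and model-comparison metrics (RMSE, MAPE, R-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
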