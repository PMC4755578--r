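Package: infomaxnet
Title: Infomax Learning of Recurrent Interactions in Sensory Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how recurrent interactions in a sensory rate
    network evolve under the infomax principle. Implements steady-state
    recurrent dynamics with a logistic nonlinearity, the susceptibility
    (Jacobian) based mutual-information objective, gradient-descent learning
    of the recurrent weight matrix with lookahead learning-rate halving, an
    analytically solvable ring (hypercolumn) model with its critical point,
    criticality metrics (convergence time, population vector, interaction
    scaling sweeps), and a natural-image training pipeline built from
    synthetic power-law textures, patch extraction, PCA whitening and a
    Gabor filter bank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
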