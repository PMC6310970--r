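Package: emdav
Title: Evolutionary Search for miRNA Feature Selection and Deep MLP
    Architecture
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint evolutionary optimisation of input-feature subsets,
    multilayer-perceptron architecture and training-validation scheme for
    nonlinear regression of a target transcript (such as mRNA-Smad7) on
    miRNA expression profiles. A variable-length binary genetic algorithm
    encodes the feature mask, the validation method (hold-out or k-fold)
    and the hidden-layer sizes of a deep multilayer perceptron trained with
    RMSprop; the selected model is refit with resilient backpropagation
    (Rprop+), and per-feature relative importance is derived from Olden's
    connection-weight products. Includes the surrounding expression-data
    pipeline: presence and quartile/mode low-information filters, discrete
    Meyer wavelet denoising, range scaling, a collinearity screen, and a
    synthetic zero-inflated expression-data generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
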