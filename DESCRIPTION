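Package: mitovox
Title: 3D Conditional GANs for Mitochondrial Event Location Prediction
Version: 0.1.0
Authors@R:
    person("mitovox", "developers", email = "mitovox@example.org", role = c("aut", "cre"))
Description: Predicts the three-dimensional locations of mitochondrial
    fission, fusion and depolarisation events from a single fluorescence
    z-stack using 3D conditional generative adversarial networks (a 3D
    Pix2Pix variant and a Vox2Vox variant) trained with an
    event-location-penalised mean absolute error (ELP-MAE) loss.  Includes
    a declarative network-architecture layer with analytic parameter
    counting and receptive-field computation, a self-contained CPU
    training engine, a synthetic fluorescence z-stack simulator emulating
    tubular mitochondrial structures and colour-coded event kernels, and
    an automated event-extraction and accuracy evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
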