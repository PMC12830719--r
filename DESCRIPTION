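Package: faudyn
Title: Facial Action-Unit Dynamics and Conversation-Context Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the social context of a conversation
    leaves a decodable trace in facial action-unit (AU) dynamics alone.
    Provides a generator for synthetic triadic AU time series with
    turn-taking speech structure, speech masking, Gramian Angular
    Difference Field (GADF) image encoding of AU signals, a compact
    convolutional classifier evaluated with leakage-free cross-group
    validation, control analyses (temporal permutation, speech-binary
    input, static-feature baselines, segment-length grids), and summary
    statistics for human-rater classification studies (accuracy levels,
    Matthews correlation, Fleiss' kappa, group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
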