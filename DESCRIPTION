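Package: guildAB
Title: Metabolic Functional Guild Detection with the Aspect Bernoulli Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the aspect Bernoulli model, a probabilistic decomposition of
    binary genome-by-function presence/absence matrices, by expectation
    maximization with random restarts. From the fitted aspects it scores and
    ranks functions, identifies metabolic functional guilds (co-occurring
    function sets) together with their mapback genomes, and quantifies guild
    specificity with association-rule confidence. Includes a planted-guild
    simulation framework for choosing the number of aspects via hit-rate and
    extra-hit diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
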