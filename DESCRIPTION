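Package: fhenet
Title: Encrypted Neural-Network Graphs with Automatic CKKS Parameterisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A node-centric framework for privacy-preserving neural-network
    inference over levelled homomorphic encryption. Networks are
    multi-directed computation graphs fired by a depth-first, blocking
    signal-propagation algorithm; a longest-path analysis over node costs
    automatically derives RNS-CKKS encryption parameters (modulus chain,
    polynomial degree, parameter groups) for every ciphertext entering the
    graph. FHE-compatible layers include masqueraded-kernel
    cross-correlation with a commuted bias, dense merge nodes, and
    polynomial ReLU/sigmoid approximations with a dynamically tracked
    range; a deterministic simulated CKKS backend enforces the scheme's
    constraints so plaintext and ciphertext runs are exactly equivalent.
    Includes builders for an image classifier and a 1D environmental
    yield-forecasting regressor, seeded synthetic data generators, and a
    command surface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
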