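Package: hoss
Title: Higher-Order State-Space Model of Awareness Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates awareness ("seen"/"unseen") reports as exact Bayesian
    inference in a two-level generative model in which a binary awareness
    state sits above discrete perceptual content states that emit Gaussian
    sensory evidence. Provides posterior inference at both levels of the
    hierarchy, Kullback-Leibler belief-update ("Bayesian surprise") analysis
    as a computational proxy for global ignition, a flat signal-detection
    comparator in which absence is an ordinary stimulus class, feature-space
    posterior and surprise maps, and a seeded backward-masking simulation in
    which stimulus-onset asynchrony is modelled as sensory precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
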