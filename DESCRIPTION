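Package: pcnlearn
Title: Prospective Configuration Learning in Predictive Coding Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Energy-based predictive coding networks that learn by
    prospective configuration: neural activity first relaxes toward the
    pattern that would follow successful learning, and Hebbian plasticity
    then consolidates that pattern. Includes a weight-matched
    backpropagation baseline sharing the same layered networks,
    interference metrics (target alignment), minimal-network simulations
    of contextual sensorimotor adaptation and reversal reinforcement
    learning with grid-search fitting, and a Q-learning loop with
    experience replay driven by either learning rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
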