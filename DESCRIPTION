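Package: interforage
Title: Optimal Interruptible Foraging Under Predation Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves a partially observable semi-Markov decision model of
    foraging under predation risk. An animal commits to temporally extended
    activities (action-duration pairs), maintains Bayesian beliefs about two
    hidden two-state Markov processes (predator presence and habitat
    quality), and pays a fixed cost per deliberation. The package provides
    the generative world simulator, exact belief filtering, value iteration
    on a discretized belief grid with and without the capacity to interrupt
    ongoing activities, matched-trial simulation experiments comparing
    interruptible and non-interruptible policies across decision costs, and
    extraction of threshold-based approximations to the optimal interruption
    rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
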