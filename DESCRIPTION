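Package: sharegame
Title: Evolutionary Game Analysis of Pandemic Information Sharing and
    Disclosure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the asymmetric 2x2 evolutionary game between online
    users, who decide whether to share personal pandemic-related information,
    and a government, which decides whether to disclose the information it
    collects.  Implements the payoff bimatrix, replicator dynamics,
    equilibrium enumeration with Jacobian-based local stability
    classification, the three parameter regimes and their stable strategy
    profiles, analytic and Monte Carlo basin-of-attraction probabilities
    with sensitivity analysis in the information-value multiplier, and
    social-efficiency (welfare) comparison of the four pure strategy
    profiles against the evolutionary outcome.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
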