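Package: ctrwtails
Title: Exact Solutions and Large-Deviation Tails for Continuous Time Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the wait-then-jump (continuous time random walk) model
    of particle spreading. Provides exact renewal counting distributions for
    exponential, Erlang and two-exponential-mixture waiting times, exact
    series propagators with Gaussian or lattice jump lengths, saddle-point
    tail asymptotics with closed-form Lambert-W saddles, large-deviation
    rate functions, the universal exponential-tail formula controlled by the
    short-time expansion of the waiting-time density, Mandel-Q
    bunching/anti-bunching diagnostics, and a seeded Monte Carlo simulator
    that serves as an independent stochastic cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
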