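Package: bloodnet
Title: Multi-Period Multi-Scenario Blood Supply Chain Network Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of an emergency blood supply chain network after a disaster:
    siting of temporary and permanent collection facilities, blood centers and
    field hospitals, with blood flow allocation, inventory and shortage
    accounting over multiple response periods. Implements a bi-objective
    mixed-integer linear program (total cost versus transfusion shortage),
    solved by a built-in branch-and-bound over a dense two-phase simplex, with
    weighted-sum and epsilon-constraint multi-objective drivers, a two-stage
    scenario-based stochastic extension with a shortage-penalty sweep and a
    worst-case (min-max) mode, a seeded synthetic instance generator, and an
    independent solution checker plus exhaustive flow-based oracles for ground
    truth on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
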