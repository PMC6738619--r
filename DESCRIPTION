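Package: kooplog
Title: Koopman Mode Analysis of Logistics Agent-Based Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Stochastic agent-based simulators for two logistics systems -- a
    casualty-flow network of medical treatment facilities and a ship-fueling
    supply network on a hexagonal grid -- together with a dynamic mode
    decomposition (DMD) core for Koopman mode analysis of their multivariate
    time series. Provides eigenvalue-distribution summaries across replicate
    sweeps, a circle-count spectral health indicator with green/yellow/red
    classification for bifurcation tracking, and the exact operator
    representation and spectrum of linearly decaying signals with random
    jumps, against which the numerically split DMD spectrum can be compared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
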