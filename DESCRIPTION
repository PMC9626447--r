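Package: eclen
Title: ATP-Driven Cell Length Dynamics of Endothelial Cells on Adhesive Line Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled stochastic model of endothelial cell length on micropatterned
    adhesive lines. Three coupled equations describe filamentous actin regulated by
    an ATP-dependent switch, cell length as an Ornstein-Uhlenbeck process whose
    reversion rate is set by actomyosin contractility, and intracellular ATP with
    stretch-induced release gated by a two-branch hysteresis relay. The package
    provides constraint-based parameter derivation from measured length statistics,
    an implicit-explicit (IMEX) integrator with Euler-Maruyama noise, prototype
    ("statistical cell") length profiles and synthetic experiment-like traces,
    particle swarm calibration of the unknown shape parameters, and
    one-at-a-time sensitivity sweeps with regime classification that discriminate
    the running, undecided, and tumbling migration phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
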