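Package: capkin
Title: Dissolution-Crystallization Kinetics of Calcium Phosphate Bone
    Grafts in Physiological Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical model of the behaviour of resorbable calcium
    phosphate bone-graft materials in physiological fluids. Solves the
    equilibrium ion speciation of simulated body fluid (SBF) and
    DMEM+serum media with Davies activity corrections and multi-site
    calcium-albumin binding; integrates the coupled brushite (DCPD)
    dissolution / octacalcium phosphate (OCP) crystallization rate model
    with surface-area feedback, Tris or carbonate pH handling, protein
    inhibition of crystal growth and periodic medium exchange;
    cross-checks the semi-empirical rate law against classical
    nucleation theory; and estimates kinetic parameters from observable
    time series by simulated annealing followed by local least squares.
    A synthetic-data generator produces daily-sampled 14-day observable
    series with Gaussian measurement noise from known ground truth, so
    the full analysis chain is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
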