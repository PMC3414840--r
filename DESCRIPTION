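Package: wallkinetics
Title: Crosslink Kinetics and Yield in the Expanding Plant Cell Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulator of hemicellulose crosslink kinetics in an
    elongating plant primary cell wall. Crosslinks tethering cellulose
    microfibrils are advected through the wall by the stretching flow,
    elongate as linear springs, and rupture at a strain-enhanced (Bell-type)
    rate; new crosslinks are deposited unstressed at the inner wall face.
    The package computes transient and steady-state stress/strain-rate
    relations by quadrature along characteristics, incorporates XET, XEH and
    expansin enzyme action, extracts effective Lockhart/Bingham yield-stress
    and extensibility parameters, maps physical wall parameters to the
    dimensionless model, and provides independent stochastic-ensemble and
    ODE verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
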