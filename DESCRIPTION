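Package: n2osink
Title: Batch-Vial Kinetics, Chamber Fluxes and Inoculant Tracking for
    N2O-Respiring Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating nitrous-oxide-respiring bacteria as soil
    N2O sinks. Processes stirred batch-vial headspace gas time series into
    loss-corrected production and consumption rates, dissolved gas
    concentrations, cell trajectories and fitted biokinetic parameters
    (maximum growth rates, Michaelis-Menten constants, growth yields,
    oxygen thresholds for N2O-respiration onset). Simulates bet-hedging
    batch cultures with an expressing and a non-expressing subpopulation
    and estimates the expressing fraction by model fitting. Computes
    dynamic-chamber N2O fluxes, Gaussian-kernel smoothed flux curves,
    trapezoid-cumulated emissions and percentage emission reductions with
    Fieller, bootstrap and Student-t confidence intervals for paired and
    unpaired designs. Calibrates and inverts an exponential qPCR
    quantification model with detection limits and inhibition checks, and
    fits first-order survival decay. Applies uniform reduction factors to
    emission inventory tables. Ships synthetic-data generators so the
    entire analysis chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
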