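Package: biofiltervoc
Title: Coupled Biofilm and Gas-Phase Modelling of VOC Biofiltration with
    an Elman Network Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state modelling of biofiltration of volatile organic
    compound mixtures (hydrophilic methanol and hydrophobic alpha-pinene)
    through a packed-bed biofilter.  Solves the nonlinear Michaelis-Menten
    reaction-diffusion boundary value problem in the biofilm, including its
    first-order (unsaturated) and zero-order (saturated) limiting regimes
    with closed-form solutions, couples the interface flux to a plug-flow
    gas-phase column model with methanol-on-pinene inhibition, trains an
    Elman recurrent network surrogate of the concentration profiles with a
    Levenberg-Marquardt optimizer, and evaluates predictions with mean
    absolute deviation, Theil's inequality coefficient and Nash-Sutcliffe
    efficiency statistics aggregated over repeated stochastic trainings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
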