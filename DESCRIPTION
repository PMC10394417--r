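Package: crnControl
Title: Antithetic Integral Feedback Control of Two-Output Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composing, simulating and certifying molecular
    sequestration (antithetic integral) controllers on mass-action chemical
    reaction networks with two output species. Provides the ratio, product,
    linear-combination and decoupling regulator motifs, closed-loop
    composition onto a mutual-activation birth-death plant, stiff ODE
    simulation with timed parameter disturbances, memory-variable traces,
    steady-state objective verification (robust perfect adaptation), and
    local stability analysis via Jacobian eigenvalues cross-checked with the
    Routh-Hurwitz criterion, including a parameter scan that exposes the
    infeasibility of a mispaired actuator-sensor configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, deSolve, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Collate:
    AllClasses.R
    AllGenerics.R
    crn-core.R
    serialize.R
    motifs.R
    scenarios.R
    simulate.R
    stability.R
    verify.R
    config-io.R
RoxygenNote: 7.3.3
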