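# Run-configuration template for crnControl.
#
# Exactly one of `scenario` (a registered id, see listScenarios()) or
# `network` (path to a JSON network written by writeNetwork()) must be
# given. All other keys are optional and shown with their defaults.

scenario: fig4a          # or: network: path/to/plant.json

# Only with `network`: close the loop with a regulator before running.
# regulator:
#   family: R            # R, R_PRODUCT, LC, D1, D2, D3, D2_MISPAIRED
#   parameters: {k1: 0.5, k2: 1, k3: 2, eta: 10}
#   extra_inhibition: false     # add Y1 + Z1 -> Z1 at rate k4 (R/LC only)
#   degradation_rate: 0         # shared controller dilution, min^-1

t_end: 500               # horizon, min; must exceed the last event time

# Timed step disturbances (replaces a scenario's built-in schedule).
# schedule:
#   - {time: 50, parameter: b1, value: 4}

# Override individual rate constants of the resolved network.
# parameters:
#   k1: 0.25

# tolerances:
#   rtol: 1.0e-8          # integrator relative tolerance
#   atol: 1.0e-10         # integrator absolute tolerance, nM
#   drift: 1.0e-6         # trailing-window relative drift for convergence
#   residual: 1.0e-8      # |rhs| threshold at the final state, nM/min
#   objective: 1.0e-4     # relative tolerance for objective pass/fail

out_dir: "."             # where writeReport() places CSV/JSON output

# Study flags picked up by the command-line front end.
rpa: false               # parameter-perturbation robustness table
degradation: false       # controller-dilution study
scan: false              # stability scan over controller parameters
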