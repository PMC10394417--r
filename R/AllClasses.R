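#' @import methods
#' @importFrom stats setNames
NULL

## Concentrations are in nM, time in minutes, throughout the package.
## Rate constants therefore carry min^-1 (first order), nM.min^-1
## (zeroth order) or nM^-1.min^-1 (second order).

#' Mass-action reaction
#'
#' A single chemical reaction with integer stoichiometry and one rate
#' constant, interpreted under mass-action kinetics: the propensity is the
#' rate constant times the product of reactant concentrations raised to
#' their stoichiometric coefficients. An empty reactant side encodes
#' zeroth-order production from the environment.
#'
#' @slot reactants Named integer vector; names are species, values are
#'   stoichiometric coefficients (all positive). May be empty.
#' @slot products Named integer vector, same convention. May be empty.
#' @slot rate Name of the rate constant in the owning network's parameter
#'   table.
#' @slot kind Annotation tag, one of `"transformation"`,
#'   `"catalytic_production"`, `"catalytic_inhibition"`, `"annihilation"`,
#'   `"zeroth_order"`. Purely descriptive; the kinetics follow from the
#'   stoichiometry alone.
#'
#' @seealso [reaction()] for the user-facing constructor.
#' @export
setClass("Reaction",
  representation(
    reactants = "integer",
    products  = "integer",
    rate      = "character",
    kind      = "character"
  )
)

.reactionKinds <- c("transformation", "catalytic_production",
                    "catalytic_inhibition", "annihilation", "zeroth_order")

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !nzchar(object@rate))
    msg <- c(msg, "'rate' must be a single non-empty parameter name")
  if (length(object@reactants) && (is.null(names(object@reactants)) ||
      any(!nzchar(names(object@reactants)))))
    msg <- c(msg, "reactants must be a named vector")
  if (length(object@products) && (is.null(names(object@products)) ||
      any(!nzchar(names(object@products)))))
    msg <- c(msg, "products must be a named vector")
  if (any(object@reactants <= 0L) || any(object@products <= 0L))
    msg <- c(msg, "stoichiometric coefficients must be positive integers")
  if (anyDuplicated(names(object@reactants)) ||
      anyDuplicated(names(object@products)))
    msg <- c(msg, "duplicate species in a reaction side; merge coefficients")
  if (length(object@kind) != 1L || !object@kind %in% .reactionKinds)
    msg <- c(msg, sprintf("'kind' must be one of: %s",
                          paste(.reactionKinds, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Mass-action reaction network
#'
#' The single container used for plants, controller fragments and closed
#' loops: an ordered species list with initial concentrations, a reaction
#' list, a table of strictly positive rate constants, and a designated set
#' of output species.
#'
#' @slot species Character vector of species names (ordered; unique).
#' @slot initial Named numeric vector of initial concentrations (nM),
#'   one per species, all >= 0.
#' @slot reactions List of [Reaction-class] objects.
#' @slot parameters Named numeric vector of rate constants, all > 0.
#' @slot outputs Character vector naming the output species (subset of
#'   `species`).
#'
#' @seealso [reactionNetwork()], [makePlant()], [closeLoop()]
#' @export
setClass("ReactionNetwork",
  representation(
    species    = "character",
    initial    = "numeric",
    reactions  = "list",
    parameters = "numeric",
    outputs    = "character"
  )
)

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@species))
    msg <- c(msg, "species names must be unique")
  if (length(object@initial) != length(object@species) ||
      !identical(names(object@initial), object@species))
    msg <- c(msg, "'initial' must be named exactly by 'species', in order")
  else if (any(object@initial < 0))
    msg <- c(msg, "initial concentrations must be non-negative")
  if (length(object@parameters) &&
      (is.null(names(object@parameters)) || any(!nzchar(names(object@parameters)))))
    msg <- c(msg, "'parameters' must be a named vector")
  if (anyDuplicated(names(object@parameters)))
    msg <- c(msg, "duplicate parameter names")
  if (any(object@parameters <= 0) || any(!is.finite(object@parameters)))
    msg <- c(msg, "all rate constants must be finite and strictly positive")
  for (i in seq_along(object@reactions)) {
    rx <- object@reactions[[i]]
    if (!is(rx, "Reaction")) {
      msg <- c(msg, sprintf("reactions[[%d]] is not a Reaction", i))
      next
    }
    bad <- setdiff(c(names(rx@reactants), names(rx@products)), object@species)
    if (length(bad))
      msg <- c(msg, sprintf("reaction %d references undeclared species: %s",
                            i, paste(bad, collapse = ", ")))
    if (!rx@rate %in% names(object@parameters))
      msg <- c(msg, sprintf("reaction %d: rate constant '%s' missing from the parameter table",
                            i, rx@rate))
  }
  if (length(object@outputs) && !all(object@outputs %in% object@species))
    msg <- c(msg, "outputs must be declared species")
  if (length(msg)) msg else TRUE
})

#' Regulator specification
#'
#' Describes one of the sequestration-based controller architectures by
#' family tag and rate constants, plus two optional augmentations: an
#' extra inhibitory reaction on the first output (for the ratio and
#' linear-combination families) and a shared first-order dilution applied
#' to every controller species.
#'
#' Families: `"R"` (output ratio), `"R_PRODUCT"` (output product),
#' `"LC"` (linear combination), `"D1"`, `"D2"`, `"D3"` (independent
#' set-points via decoupling), and `"D2_MISPAIRED"` (the D2 architecture
#' with the two annihilation pairs swapped, which destabilises the loop).
#'
#' @slot family Family tag (see above).
#' @slot parameters Named numeric vector of the family's rate constants.
#' @slot extraInhibition Logical; add `Y1 + Z1 -> Z1` at rate `k4`
#'   (families R and LC only).
#' @slot degradationRate Non-negative dilution rate (min^-1) appended as
#'   first-order decay of every controller species; 0 disables it.
#'
#' @seealso [regulatorSpec()], [makeRegulator()], [predictedSetpoint()]
#' @export
setClass("RegulatorSpec",
  representation(
    family          = "character",
    parameters      = "numeric",
    extraInhibition = "logical",
    degradationRate = "numeric"
  )
)

.regulatorFamilies <- c("R", "R_PRODUCT", "LC", "D1", "D2", "D3", "D2_MISPAIRED")

.familyParams <- list(
  R            = c("k1", "k2", "k3", "eta"),
  R_PRODUCT    = c("k1", "k2", "k3", "eta"),
  LC           = c("k1", "k2", "k3", "eta", "theta1", "theta2"),
  D1           = c("k1", "k2", "k3", "k4", "eta1", "eta2", "theta1", "theta2"),
  D2           = c("k1", "k2", "k3", "k4", "eta1", "eta2", "theta1", "theta2"),
  D2_MISPAIRED = c("k1", "k2", "k3", "k4", "eta1", "eta2", "theta1", "theta2"),
  D3           = c("k1", "k2", "k3", "k4", "eta1", "eta2", "theta1")
)

setValidity("RegulatorSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% .regulatorFamilies)
    return(sprintf("unknown regulator family; use one of: %s",
                   paste(.regulatorFamilies, collapse = ", ")))
  need <- .familyParams[[object@family]]
  if (object@extraInhibition) {
    if (!object@family %in% c("R", "LC"))
      msg <- c(msg, "extraInhibition is only defined for families R and LC")
    need <- union(need, "k4")
  }
  missing <- setdiff(need, names(object@parameters))
  if (length(missing))
    msg <- c(msg, sprintf("family %s requires parameters: %s",
                          object@family, paste(missing, collapse = ", ")))
  if (any(object@parameters <= 0) || any(!is.finite(object@parameters)))
    msg <- c(msg, "all regulator rate constants must be finite and positive")
  if (length(object@degradationRate) != 1L || object@degradationRate < 0 ||
      !is.finite(object@degradationRate))
    msg <- c(msg, "degradationRate must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Closed-loop network
#'
#' A [ReactionNetwork-class] formed by merging a plant with a regulator:
#' sensing reactions read the plant's designated outputs and actuation
#' reactions act on them. Carries the provenance needed by downstream
#' verification (which regulator family, which plant species play the two
#' targets).
#'
#' @slot regulator The [RegulatorSpec-class] the loop was closed with.
#' @slot targetMap Named character vector mapping the abstract targets
#'   `Y1`, `Y2` to plant species names.
#' @slot plantSpecies Character vector of the plant's species (the
#'   remaining species belong to the controller).
#'
#' @seealso [closeLoop()]
#' @export
setClass("ClosedLoopNetwork",
  contains = "ReactionNetwork",
  representation(
    regulator    = "RegulatorSpec",
    targetMap    = "character",
    plantSpecies = "character"
  )
)

setValidity("ClosedLoopNetwork", function(object) {
  msg <- character()
  if (!identical(sort(names(object@targetMap)), c("Y1", "Y2")))
    msg <- c(msg, "targetMap must map exactly Y1 and Y2")
  if (!all(object@targetMap %in% object@species))
    msg <- c(msg, "targetMap points at undeclared species")
  if (!all(object@plantSpecies %in% object@species))
    msg <- c(msg, "plantSpecies must be declared species")
  if (length(msg)) msg else TRUE
})

#' Timed parameter disturbances
#'
#' An ordered list of step changes to named rate constants: at each event
#' time the parameter jumps instantaneously to its new value and
#' integration resumes from the current state.
#'
#' @slot events data.frame with columns `time` (min, strictly increasing,
#'   > 0), `parameter` (name) and `value` (new rate constant, > 0).
#'
#' @seealso [disturbanceSchedule()], [simulateNetwork()]
#' @export
setClass("DisturbanceSchedule",
  representation(events = "data.frame")
)

setValidity("DisturbanceSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("time", "parameter", "value") %in% names(ev)))
    return("events must have columns time, parameter, value")
  if (nrow(ev)) {
    if (any(ev$time <= 0)) msg <- c(msg, "event times must be > 0")
    if (is.unsorted(ev$time, strictly = TRUE))
      msg <- c(msg, "event times must be strictly increasing")
    if (any(ev$value <= 0) || any(!is.finite(ev$value)))
      msg <- c(msg, "event values must be finite and > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation result
#'
#' Trajectories of a (closed-loop) network on a time grid, together with
#' the steady-state snapshot taken over the trailing window, a convergence
#' flag, the memory-variable traces of the regulator family (if any), and
#' the parameter table in force at the end of the run.
#'
#' @slot times Numeric time grid (min).
#' @slot trajectories Numeric matrix, one column per species (nM).
#' @slot steadyState Named numeric vector: mean concentration over the
#'   trailing window.
#' @slot converged Logical; TRUE when both the trailing relative drift and
#'   the right-hand-side residual fell below tolerance.
#' @slot residual Max-norm of the ODE right-hand side at the final state
#'   (nM/min).
#' @slot memoryTraces Named list of derived series (e.g. `Z1 - Z2`).
#' @slot finalParameters Parameter table after all disturbance events.
#' @slot clipped Number of trajectory entries clipped up to zero.
#' @slot notes Character diagnostics (integration warnings etc.).
#'
#' @seealso [simulateNetwork()], [memoryTrace()]
#' @export
setClass("SimulationResult",
  representation(
    times           = "numeric",
    trajectories    = "matrix",
    steadyState     = "numeric",
    converged       = "logical",
    residual        = "numeric",
    memoryTraces    = "list",
    finalParameters = "numeric",
    clipped         = "numeric",
    notes           = "character"
  )
)

#' Local stability report
#'
#' Output of [assessStability()]: the located non-negative equilibrium,
#' the Jacobian eigenvalues (the authoritative test), the monic
#' characteristic polynomial, and the Routh-Hurwitz verdict used as a
#' cross-check.
#'
#' @slot equilibrium Named numeric equilibrium vector (nM).
#' @slot eigenvalues Complex eigenvalues of the Jacobian at equilibrium.
#' @slot charPoly Real coefficients of the monic characteristic
#'   polynomial, descending powers.
#' @slot verdict `"stable"`, `"unstable"` or `"marginal"`.
#' @slot notes Character; method notes.
#'
#' @export
setClass("StabilityReport",
  representation(
    equilibrium = "numeric",
    eigenvalues = "complex",
    charPoly    = "numeric",
    verdict     = "character",
    notes       = "character"
  )
)

#' Steady-state objective check
#'
#' Result of comparing a simulated steady state against the set-point
#' guaranteed by the regulator family's memory variables.
#'
#' @slot kind `"ratio"`, `"product"`, `"lincomb"` or `"setpoints"`.
#' @slot target Named numeric target value(s).
#' @slot achieved Named numeric achieved value(s).
#' @slot absResidual Absolute residual(s).
#' @slot relResidual Relative residual(s).
#' @slot pass Logical; all relative residuals within tolerance.
#' @slot tolerance Relative tolerance used.
#'
#' @seealso [checkObjective()]
#' @export
setClass("ObjectiveResult",
  representation(
    kind        = "character",
    target      = "numeric",
    achieved    = "numeric",
    absResidual = "numeric",
    relResidual = "numeric",
    pass        = "logical",
    tolerance   = "numeric"
  )
)
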