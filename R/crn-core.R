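#' @include AllGenerics.R
NULL

## ---- constructors ----------------------------------------------------------

.asStoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(), character()))
  if (is.null(names(x))) stop("'", what, "' must be a named vector", call. = FALSE)
  if (any(abs(x - round(x)) > 0)) stop("'", what, "' coefficients must be integers", call. = FALSE)
  # merge duplicated species (Y1 + Y1 -> 2 Y1)
  x <- tapply(as.integer(round(x)), names(x), sum)
  setNames(as.integer(x), names(x))
}

#' Construct a mass-action reaction
#'
#' @param reactants Named integer vector of reactant coefficients; `NULL`
#'   or empty for zeroth-order production. A character vector is accepted
#'   as shorthand for unit coefficients (`c("Y1", "Z1")` means Y1 + Z1).
#' @param products As `reactants`, for the product side.
#' @param rate Name of the rate constant.
#' @param kind Annotation tag; inferred from the stoichiometry when
#'   omitted.
#' @return A [Reaction-class] object.
#' @examples
#' reaction(c(Z1 = 1, Z2 = 1), NULL, "eta")          # annihilation
#' reaction("Y1", c("Y1", "Z1"), "k1")               # catalytic production
#' @export
reaction <- function(reactants, products, rate, kind = NULL) {
  toVec <- function(x) {
    if (is.character(x)) x <- setNames(rep(1L, length(x)), x)
    x
  }
  reactants <- .asStoich(toVec(reactants), "reactants")
  products  <- .asStoich(toVec(products), "products")
  if (is.null(kind)) {
    kind <- if (length(reactants) == 0L) "zeroth_order"
    else if (length(products) == 0L) "annihilation"
    else {
      common <- intersect(names(reactants), names(products))
      if (length(common) && setequal(names(reactants), common) &&
          length(products) > length(reactants)) "catalytic_production"
      else if (length(common) && setequal(names(products), common) &&
               length(reactants) > length(products)) "catalytic_inhibition"
      else "transformation"
    }
  }
  new("Reaction", reactants = reactants, products = products,
      rate = as.character(rate), kind = kind)
}

#' Construct a reaction network
#'
#' @param species Character vector of species names, or a named numeric
#'   vector of initial concentrations (nM).
#' @param reactions List of [Reaction-class] objects.
#' @param parameters Named numeric vector of strictly positive rate
#'   constants covering every rate referenced by `reactions`.
#' @param outputs Character vector of designated output species.
#' @param initial Optional named numeric vector of initial concentrations;
#'   unnamed species default to 0 nM.
#' @return A validated [ReactionNetwork-class].
#' @export
reactionNetwork <- function(species, reactions, parameters,
                            outputs = character(), initial = NULL) {
  if (is.numeric(species) && !is.null(names(species))) {
    initial <- species
    species <- names(species)
  }
  init <- setNames(numeric(length(species)), species)
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), species)
    if (length(bad))
      stop("initial concentrations for undeclared species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    init[names(initial)] <- initial
  }
  new("ReactionNetwork", species = species, initial = init,
      reactions = reactions, parameters = parameters,
      outputs = as.character(outputs))
}

#' Construct a regulator specification
#'
#' @param family One of `"R"`, `"R_PRODUCT"`, `"LC"`, `"D1"`, `"D2"`,
#'   `"D3"`, `"D2_MISPAIRED"`.
#' @param ... Rate constants of the family, e.g. `k1 = 0.5, k2 = 1,
#'   k3 = 2, eta = 10`; alternatively a single named vector/list.
#' @param extraInhibition Add the inhibitory reaction `Y1 + Z1 -> Z1` at
#'   rate `k4` (families R and LC only).
#' @param degradationRate Shared first-order dilution (min^-1) of every
#'   controller species; default 0 (ideal motif).
#' @return A validated [RegulatorSpec-class].
#' @examples
#' regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10)
#' @export
regulatorSpec <- function(family, ..., extraInhibition = FALSE,
                          degradationRate = 0) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && (is.list(dots[[1]]) || length(dots[[1]]) > 1L) &&
       !is.null(names(dots[[1]]))))
    dots <- as.list(dots[[1]])
  params <- unlist(dots)
  new("RegulatorSpec", family = family,
      parameters = setNames(as.numeric(params), names(params)),
      extraInhibition = isTRUE(extraInhibition),
      degradationRate = as.numeric(degradationRate))
}

#' Construct a disturbance schedule
#'
#' @param time Numeric vector of event times (min), strictly increasing.
#' @param parameter Character vector of parameter names, recycled.
#' @param value Numeric vector of new values.
#' @return A [DisturbanceSchedule-class]. With no arguments, an empty
#'   schedule.
#' @examples
#' disturbanceSchedule(50, "b1", 4)   # b1 steps from its value to 4 at t = 50
#' @export
disturbanceSchedule <- function(time = numeric(), parameter = character(),
                                value = numeric()) {
  new("DisturbanceSchedule",
      events = data.frame(time = as.numeric(time),
                          parameter = as.character(parameter),
                          value = as.numeric(value),
                          stringsAsFactors = FALSE))
}

## ---- accessors -------------------------------------------------------------

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species)

#' @rdname reactions
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)

#' @rdname rateConstants
#' @export
setMethod("rateConstants", "ReactionNetwork", function(x) x@parameters)

#' @rdname rateConstants-set
#' @export
setReplaceMethod("rateConstants", "ReactionNetwork", function(x, value) {
  bad <- setdiff(names(value), names(x@parameters))
  if (length(bad))
    stop("unknown rate constants: ", paste(bad, collapse = ", "), call. = FALSE)
  x@parameters[names(value)] <- value
  validObject(x)
  x
})

#' @rdname outputSpecies
#' @export
setMethod("outputSpecies", "ReactionNetwork", function(x) x@outputs)

#' @rdname initialState
#' @export
setMethod("initialState", "ReactionNetwork", function(x) x@initial)

#' @rdname initialState-set
#' @export
setReplaceMethod("initialState", "ReactionNetwork", function(x, value) {
  bad <- setdiff(names(value), x@species)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  x@initial[names(value)] <- value
  validObject(x)
  x
})

## ---- core operations -------------------------------------------------------

#' @rdname stoichiometryMatrix
#' @export
setMethod("stoichiometryMatrix", "ReactionNetwork", function(x) {
  S <- matrix(0L, nrow = length(x@species), ncol = length(x@reactions),
              dimnames = list(x@species,
                              vapply(x@reactions, function(r) r@rate, "")))
  for (j in seq_along(x@reactions)) {
    rx <- x@reactions[[j]]
    bad <- setdiff(c(names(rx@reactants), names(rx@products)), x@species)
    if (length(bad))
      stop("reaction ", j, " references undeclared species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    S[names(rx@reactants), j] <- S[names(rx@reactants), j] - rx@reactants
    S[names(rx@products), j]  <- S[names(rx@products), j] + rx@products
  }
  S
})

#' Mass-action reaction rates at a state
#'
#' Evaluates every reaction's propensity, `rate constant x prod(conc^coef)`
#' over its reactants; zeroth-order reactions return the bare constant.
#'
#' @param net A [ReactionNetwork-class].
#' @param state Numeric concentration vector (nM), in species order (a
#'   named vector is reordered by name), all entries >= 0.
#' @param parameters Optional override of the network's rate-constant
#'   table (named numeric, full table).
#' @return Numeric vector of reaction rates (nM/min).
#' @export
rateVector <- function(net, state, parameters = NULL) {
  state <- .orderState(net, state)
  if (any(state < 0))
    stop("negative concentration in 'state'", call. = FALSE)
  p <- if (is.null(parameters)) net@parameters else parameters
  vapply(net@reactions, function(rx) {
    r <- p[[rx@rate]]
    if (length(rx@reactants)) {
      idx <- match(names(rx@reactants), net@species)
      r <- r * prod(state[idx]^as.numeric(rx@reactants))
    }
    r
  }, numeric(1))
}

.orderState <- function(net, state) {
  if (length(state) != length(net@species))
    stop("state length ", length(state), " != ", length(net@species),
         " species", call. = FALSE)
  if (!is.null(names(state))) state <- state[net@species]
  unname(state)
}

#' Deterministic rate equations of a network
#'
#' Compiles the network once into its stoichiometry matrix and a
#' mass-action rate evaluator and returns the ODE right-hand side,
#' `f(state, parameters) = S %*% rates(state)`.
#'
#' @param net A [ReactionNetwork-class].
#' @return A function `f(state, parameters = rateConstants(net))`
#'   returning the named derivative vector (nM/min).
#' @export
odeRHS <- function(net) {
  S <- stoichiometryMatrix(net)
  storage.mode(S) <- "double"
  nsp <- length(net@species)
  ridx <- lapply(net@reactions, function(rx) match(names(rx@reactants), net@species))
  rcoef <- lapply(net@reactions, function(rx) as.numeric(rx@reactants))
  pidx <- match(vapply(net@reactions, function(rx) rx@rate, ""),
                names(net@parameters))
  defaultP <- net@parameters
  spn <- net@species
  function(state, parameters = defaultP) {
    state <- .orderState(net, state)
    rates <- parameters[pidx]
    for (j in seq_along(ridx)) {
      ij <- ridx[[j]]
      if (length(ij))
        rates[j] <- rates[j] * prod(state[ij]^rcoef[[j]])
    }
    setNames(as.vector(S %*% rates), spn)
  }
}

#' Analytic Jacobian of the mass-action rate equations
#'
#' Mass-action right-hand sides are polynomial, so the Jacobian is exact:
#' d(rate_j)/d(x_m) = k_j * s_mj * x_m^(s_mj - 1) * prod over other
#' reactants, and J = S %*% d(rates)/d(x).
#'
#' @param net A [ReactionNetwork-class].
#' @param state Concentration vector (nM), species order.
#' @param parameters Optional rate-constant override.
#' @return Square numeric matrix with species dimnames.
#' @export
jacobianMatrix <- function(net, state, parameters = NULL) {
  state <- .orderState(net, state)
  p <- if (is.null(parameters)) net@parameters else parameters
  S <- stoichiometryMatrix(net)
  storage.mode(S) <- "double"
  n <- length(net@species)
  dR <- matrix(0, nrow = length(net@reactions), ncol = n)
  for (j in seq_along(net@reactions)) {
    rx <- net@reactions[[j]]
    if (!length(rx@reactants)) next
    idx <- match(names(rx@reactants), net@species)
    coef <- as.numeric(rx@reactants)
    for (m in seq_along(idx)) {
      d <- p[[rx@rate]] * coef[m] * state[idx[m]]^(coef[m] - 1)
      others <- setdiff(seq_along(idx), m)
      if (length(others))
        d <- d * prod(state[idx[others]]^coef[others])
      dR[j, idx[m]] <- d
    }
  }
  J <- S %*% dR
  dimnames(J) <- list(net@species, net@species)
  J
}

## ---- show methods ----------------------------------------------------------

.formatReaction <- function(rx) {
  side <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v > 1L, paste0(v, " ", names(v)), names(v)), collapse = " + ")
  }
  sprintf("%s -> %s  @ %s", side(rx@reactants), side(rx@products), rx@rate)
}

setMethod("show", "Reaction", function(object) {
  cat("Reaction:", .formatReaction(object), sprintf("[%s]\n", object@kind))
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(class(object), "with", length(object@species), "species and",
      length(object@reactions), "reactions\n")
  cat("species:", paste(object@species, collapse = ", "), "\n")
  if (length(object@outputs))
    cat("outputs:", paste(object@outputs, collapse = ", "), "\n")
  for (rx in object@reactions) cat(" ", .formatReaction(rx), "\n")
  cat("rate constants:\n")
  print(object@parameters)
  if (is(object, "ClosedLoopNetwork"))
    cat("regulator family:", object@regulator@family, "\n")
})

setMethod("show", "RegulatorSpec", function(object) {
  cat("RegulatorSpec family", object@family, "\n")
  print(object@parameters)
  if (object@extraInhibition) cat("with extra inhibition on Y1 (rate k4)\n")
  if (object@degradationRate > 0)
    cat("controller dilution:", object@degradationRate, "min^-1\n")
})

setMethod("show", "DisturbanceSchedule", function(object) {
  if (!nrow(object@events)) cat("DisturbanceSchedule: (empty)\n")
  else {
    cat("DisturbanceSchedule:\n")
    print(object@events)
  }
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@times), "time points,",
      ncol(object@trajectories), "species;",
      if (object@converged) "converged" else "NOT converged",
      sprintf("(|rhs|_inf = %.3g nM/min)\n", object@residual))
  cat("steady-state snapshot (nM):\n")
  print(round(object@steadyState, 6))
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport:", object@verdict, "\n")
  cat("equilibrium (nM):\n")
  print(round(object@equilibrium, 6))
  cat("eigenvalue real parts:",
      paste(sprintf("%.4g", Re(object@eigenvalues)), collapse = ", "), "\n")
})

setMethod("show", "ObjectiveResult", function(object) {
  cat("ObjectiveResult [", object@kind, "]:",
      if (all(object@pass)) "PASS" else "FAIL", "\n")
  print(data.frame(target = object@target, achieved = object@achieved,
                   rel_residual = object@relResidual))
})
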