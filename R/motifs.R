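#' @include serialize.R
NULL

#' Mutual-activation birth-death plant
#'
#' The two-output open-loop process: each output Y1, Y2 is produced at a
#' constant rate, degrades first-order, and catalyses the formation of
#' the other, giving the rate equations
#' `dY1/dt = b1 - d1*Y1 + alpha1*Y2`, `dY2/dt = b2 - d2*Y2 + alpha2*Y1`.
#'
#' @param b1,b2 Zeroth-order production rates (nM/min).
#' @param d1,d2 Degradation rates (1/min).
#' @param alpha1 Rate at which Y2 catalyses Y1 production (1/min).
#' @param alpha2 Rate at which Y1 catalyses Y2 production (1/min).
#' @return A [ReactionNetwork-class] with species Y1, Y2 (both designated
#'   outputs) and six reactions.
#' @examples
#' makePlant(b1 = 2, b2 = 1, d1 = 1, d2 = 1, alpha1 = 0.1, alpha2 = 0.4)
#' @export
makePlant <- function(b1, b2, d1, d2, alpha1, alpha2) {
  p <- c(b1 = b1, b2 = b2, d1 = d1, d2 = d2, alpha1 = alpha1, alpha2 = alpha2)
  if (any(p <= 0) || any(!is.finite(p)))
    stop("all plant parameters must be finite and strictly positive",
         call. = FALSE)
  reactionNetwork(
    species = c("Y1", "Y2"),
    reactions = list(
      reaction(NULL, "Y1", "b1"),
      reaction(NULL, "Y2", "b2"),
      reaction("Y1", NULL, "d1", kind = "transformation"),
      reaction("Y2", NULL, "d2", kind = "transformation"),
      reaction("Y1", c("Y1", "Y2"), "alpha2"),
      reaction("Y2", c("Y1", "Y2"), "alpha1")
    ),
    parameters = p,
    outputs = c("Y1", "Y2")
  )
}

#' Closed-form steady state of the open-loop plant
#'
#' The plant has a unique positive, globally exponentially stable
#' equilibrium whenever `d1*d2 > alpha1*alpha2`:
#' `Y1* = (alpha1*b2 + b1*d2) / (d1*d2 - alpha1*alpha2)` and
#' `Y2* = (alpha2*b1 + b2*d1) / (d1*d2 - alpha1*alpha2)`.
#'
#' @inheritParams makePlant
#' @return Named numeric vector `c(Y1, Y2)` (nM).
#' @export
plantSteadyState <- function(b1, b2, d1, d2, alpha1, alpha2) {
  if (d1 * d2 <= alpha1 * alpha2)
    stop("no positive stable equilibrium: requires d1*d2 > alpha1*alpha2",
         call. = FALSE)
  den <- d1 * d2 - alpha1 * alpha2
  c(Y1 = (alpha1 * b2 + b1 * d2) / den,
    Y2 = (alpha2 * b1 + b2 * d1) / den)
}

## Controller fragments are written against the abstract targets Y1/Y2 and
## bound to a plant's designated outputs by closeLoop().
.regulatorFragment <- function(spec) {
  p <- spec@parameters
  frag <- switch(spec@family,
    R = list(
      species = c("Z1", "Z2"),
      reactions = list(
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(c("Y2", "Z2"), "Z2", "k3"),
        reaction(c("Z1", "Z2"), NULL, "eta")
      )),
    R_PRODUCT = list(
      species = c("Z1", "Z2"),
      reactions = list(
        reaction(NULL, "Z1", "k1"),
        reaction(c("Y1", "Y2"), "Z2", "k2", kind = "transformation"),
        reaction(c("Y2", "Z2"), "Z2", "k3"),
        reaction(c("Z1", "Z2"), NULL, "eta")
      )),
    LC = list(
      species = c("Z1", "Z2"),
      reactions = list(
        reaction(NULL, "Z1", "theta1"),
        reaction(NULL, "Z2", "theta2"),
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(c("Y2", "Z2"), "Z2", "k3"),
        reaction(c("Z1", "Z2"), NULL, "eta")
      )),
    D1 = list(
      species = c("Z1", "Z2", "Z3", "Z4"),
      reactions = list(
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(c("Y1", "Z1"), "Z1", "k3"),
        reaction(c("Y2", "Z2"), "Z2", "k4"),
        reaction(NULL, "Z3", "theta1"),
        reaction(NULL, "Z4", "theta2"),
        reaction(c("Z1", "Z3"), NULL, "eta1"),
        reaction(c("Z2", "Z4"), NULL, "eta2")
      )),
    D2 = list(
      species = c("Z1", "Z2", "Z3", "Z4"),
      reactions = list(
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(NULL, "Z3", "theta1"),
        reaction(NULL, "Z4", "theta2"),
        reaction("Z3", c("Z3", "Y1"), "k3"),
        reaction("Z4", c("Z4", "Y2"), "k4"),
        reaction(c("Z1", "Z3"), NULL, "eta1"),
        reaction(c("Z2", "Z4"), NULL, "eta2")
      )),
    D2_MISPAIRED = list(
      species = c("Z1", "Z2", "Z3", "Z4"),
      reactions = list(
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(NULL, "Z3", "theta1"),
        reaction(NULL, "Z4", "theta2"),
        reaction("Z3", c("Z3", "Y1"), "k3"),
        reaction("Z4", c("Z4", "Y2"), "k4"),
        # annihilation pairs swapped relative to D2: the Y1-side sensor Z1
        # is compared against the Y2-side reference Z4, and vice versa
        reaction(c("Z1", "Z4"), NULL, "eta1"),
        reaction(c("Z2", "Z3"), NULL, "eta2")
      )),
    D3 = list(
      species = c("Z1", "Z2", "Z3", "C"),
      reactions = list(
        reaction("Y1", c("Y1", "Z1"), "k1"),
        reaction("Y2", c("Y2", "Z2"), "k2"),
        reaction(NULL, "Z3", "theta1"),
        reaction("Z3", c("Z3", "Y1"), "k3"),
        reaction(c("Y2", "Z2"), "Z2", "k4"),
        reaction(c("Z1", "Z3"), "C", "eta1", kind = "annihilation"),
        reaction(c("Z2", "C"), NULL, "eta2")
      )),
    stop("unknown regulator family: ", spec@family, call. = FALSE)
  )
  if (spec@extraInhibition)
    frag$reactions <- c(frag$reactions,
                        list(reaction(c("Y1", "Z1"), "Z1", "k4")))
  if (spec@degradationRate > 0) {
    frag$reactions <- c(frag$reactions, lapply(frag$species, function(s)
      reaction(s, NULL, "delta", kind = "transformation")))
  }
  frag
}

#' Controller reaction fragment of a regulator family
#'
#' Returns the family's species and reactions written against the
#' abstract targets `Y1`, `Y2` (bound to a concrete plant at
#' [closeLoop()] time). With `degradationRate > 0` in the spec, a shared
#' first-order decay `X -> 0` at rate `delta` is appended for every
#' controller species — the non-ideal (dilution) variant of the motif.
#'
#' @param spec A [RegulatorSpec-class].
#' @return A [ReactionNetwork-class] containing the controller species
#'   plus placeholder targets Y1, Y2 (initials 0), with outputs unset.
#' @export
makeRegulator <- function(spec) {
  validObject(spec)
  frag <- .regulatorFragment(spec)
  params <- spec@parameters
  if (spec@degradationRate > 0)
    params <- c(params, delta = spec@degradationRate)
  reactionNetwork(
    species = c("Y1", "Y2", frag$species),
    reactions = frag$reactions,
    parameters = params
  )
}

#' Close the loop: compose a regulator onto a plant
#'
#' Merges the controller fragment with the plant: sensing reactions read
#' the plant's two designated outputs and actuation reactions act on
#' them. Parameter tables are united; on a name collision the controller
#' parameter is namespaced with a `"ctrl."` prefix (no collision occurs
#' for any of the built-in scenarios).
#'
#' @param plant A [ReactionNetwork-class] with exactly two designated
#'   outputs (first plays Y1, second plays Y2).
#' @param spec A [RegulatorSpec-class].
#' @return A [ClosedLoopNetwork-class].
#' @examples
#' plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
#' closeLoop(plant, regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10))
#' @export
closeLoop <- function(plant, spec) {
  validObject(plant)
  validObject(spec)
  outs <- outputSpecies(plant)
  if (length(outs) != 2L)
    stop("plant must designate exactly two output species", call. = FALSE)
  targetMap <- c(Y1 = outs[[1]], Y2 = outs[[2]])
  frag <- .regulatorFragment(spec)

  ctrlSpecies <- frag$species
  clash <- intersect(ctrlSpecies, plant@species)
  if (length(clash))
    stop("controller species collide with plant species: ",
         paste(clash, collapse = ", "), call. = FALSE)

  ctrlParams <- spec@parameters
  if (spec@degradationRate > 0)
    ctrlParams <- c(ctrlParams, delta = spec@degradationRate)
  rename <- intersect(names(ctrlParams), names(plant@parameters))
  renameMap <- setNames(names(ctrlParams), names(ctrlParams))
  if (length(rename)) {
    renameMap[rename] <- paste0("ctrl.", rename)
    names(ctrlParams) <- renameMap[names(ctrlParams)]
  }

  bind <- function(v) {
    if (!length(v)) return(v)
    nm <- names(v)
    nm[nm == "Y1"] <- targetMap[["Y1"]]
    nm[nm == "Y2"] <- targetMap[["Y2"]]
    setNames(v, nm)
  }
  rxs <- lapply(frag$reactions, function(rx)
    new("Reaction", reactants = bind(rx@reactants),
        products = bind(rx@products),
        rate = renameMap[[rx@rate]], kind = rx@kind))

  net <- new("ClosedLoopNetwork",
    species    = c(plant@species, ctrlSpecies),
    initial    = c(plant@initial,
                   setNames(numeric(length(ctrlSpecies)), ctrlSpecies)),
    reactions  = c(plant@reactions, rxs),
    parameters = c(plant@parameters, ctrlParams),
    outputs    = outs,
    regulator  = spec,
    targetMap  = targetMap,
    plantSpecies = plant@species)
  validObject(net)
  net
}

#' Guaranteed steady-state objective of a regulator
#'
#' The memory variables of each family force a steady-state relation on
#' the outputs, independent of the plant (given closed-loop stability):
#' \describe{
#'   \item{R}{ratio `Y1*/Y2* = k2/k1`}
#'   \item{R_PRODUCT}{product `Y1* x Y2* = k1/k2`}
#'   \item{LC}{linear combination `k1*Y1* - k2*Y2* = theta2 - theta1`}
#'   \item{D1, D2}{set-points `Y1* = theta1/k1`, `Y2* = theta2/k2`}
#'   \item{D3}{set-points `Y1* = theta1/k1`, `Y2* = theta1/k2`}
#' }
#'
#' @param spec A [RegulatorSpec-class].
#' @return List with elements `kind` (`"ratio"`, `"product"`,
#'   `"lincomb"`, `"setpoints"`), `target` (named numeric), and for
#'   `"lincomb"` also `weights` (named numeric applied to Y1, Y2).
#' @export
predictedSetpoint <- function(spec) {
  validObject(spec)
  p <- spec@parameters
  switch(spec@family,
    R = list(kind = "ratio",
             target = c(ratio = unname(p[["k2"]] / p[["k1"]]))),
    R_PRODUCT = list(kind = "product",
                     target = c(product = unname(p[["k1"]] / p[["k2"]]))),
    LC = list(kind = "lincomb",
              target = c(lincomb = unname(p[["theta2"]] - p[["theta1"]])),
              weights = c(Y1 = unname(p[["k1"]]), Y2 = -unname(p[["k2"]]))),
    D1 = ,
    D2 = ,
    D2_MISPAIRED = list(kind = "setpoints",
              target = c(Y1 = unname(p[["theta1"]] / p[["k1"]]),
                         Y2 = unname(p[["theta2"]] / p[["k2"]]))),
    D3 = list(kind = "setpoints",
              target = c(Y1 = unname(p[["theta1"]] / p[["k1"]]),
                         Y2 = unname(p[["theta1"]] / p[["k2"]])))
  )
}
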