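#' @include AllClasses.R
NULL

#' Species names of a network
#' @param x A [ReactionNetwork-class].
#' @return Character vector of species names, in declaration order.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Reactions of a network
#' @param x A [ReactionNetwork-class].
#' @return List of [Reaction-class] objects.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' Rate-constant table
#' @param x A [ReactionNetwork-class].
#' @return Named numeric vector of rate constants.
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))

#' Replace rate constants
#' @param x A [ReactionNetwork-class].
#' @param value Named numeric vector; names must already exist in the table.
#' @export
setGeneric("rateConstants<-", function(x, value) standardGeneric("rateConstants<-"))

#' Output species of a network
#' @param x A [ReactionNetwork-class].
#' @return Character vector of designated output species.
#' @export
setGeneric("outputSpecies", function(x) standardGeneric("outputSpecies"))

#' Initial concentrations
#' @param x A [ReactionNetwork-class].
#' @return Named numeric vector (nM).
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' Replace initial concentrations
#' @param x A [ReactionNetwork-class].
#' @param value Named numeric vector; a subset of species may be given.
#' @export
setGeneric("initialState<-", function(x, value) standardGeneric("initialState<-"))

#' Stoichiometry matrix
#'
#' Net-production matrix of a network: entry (i, j) is the net number of
#' molecules of species i produced by one firing of reaction j (products
#' minus reactants). Catalysts — species appearing with equal coefficients
#' on both sides — get a zero entry.
#'
#' @param x A [ReactionNetwork-class].
#' @return Integer matrix, species x reactions, with dimnames.
#' @export
setGeneric("stoichiometryMatrix", function(x) standardGeneric("stoichiometryMatrix"))
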