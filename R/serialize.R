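#' @include crn-core.R
NULL

## JSON serialization of networks. Units are derived from reaction order
## (0 -> nM.min^-1, 1 -> min^-1, 2 -> nM^-1.min^-1) and written for human
## readers; they are redundant on read.

.paramUnits <- function(net) {
  units <- setNames(rep(NA_character_, length(net@parameters)),
                    names(net@parameters))
  for (rx in net@reactions) {
    ord <- sum(rx@reactants)
    u <- switch(as.character(ord), "0" = "nM.min^-1", "1" = "min^-1",
                sprintf("nM^-%d.min^-1", ord - 1L))
    units[[rx@rate]] <- u
  }
  units
}

#' Write a network to JSON
#'
#' Serializes species (name + initial concentration), reactions
#' (reactant/product stoichiometry, rate-constant name, kind), the
#' parameter table with derived units, and the designated outputs. The
#' representation round-trips losslessly through [readNetwork()].
#'
#' @param net A [ReactionNetwork-class].
#' @param path File path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
writeNetwork <- function(net, path = NULL) {
  units <- .paramUnits(net)
  obj <- list(
    species = lapply(net@species, function(s)
      list(name = s, initial = net@initial[[s]])),
    reactions = lapply(net@reactions, function(rx) list(
      reactants = as.list(rx@reactants),
      products  = as.list(rx@products),
      rate      = rx@rate,
      kind      = rx@kind)),
    parameters = lapply(names(net@parameters), function(p)
      list(name = p, value = net@parameters[[p]], units = units[[p]])),
    outputs = as.list(net@outputs)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path File path, or a JSON string produced by [writeNetwork()].
#' @return A validated [ReactionNetwork-class].
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  species <- vapply(obj$species, function(s) s$name, "")
  initial <- setNames(vapply(obj$species, function(s) as.numeric(s$initial),
                             numeric(1)), species)
  rxs <- lapply(obj$reactions, function(r) {
    toVec <- function(x) setNames(as.integer(unlist(x)), names(x))
    reaction(toVec(r$reactants), toVec(r$products), r$rate, kind = r$kind)
  })
  params <- setNames(vapply(obj$parameters, function(p) as.numeric(p$value),
                            numeric(1)),
                     vapply(obj$parameters, function(p) p$name, ""))
  reactionNetwork(species, rxs, params,
                  outputs = as.character(unlist(obj$outputs)),
                  initial = initial)
}
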