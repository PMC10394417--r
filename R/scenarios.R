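#' @include motifs.R
NULL

## Every bundled simulation case, keyed by the figure id it reproduces. All
## rate constants are the case's reference values (nM, min units); each case
## applies the same step disturbance b1: 2 -> 4 at t = 50 min.

.basePlant <- function()
  makePlant(b1 = 2, b2 = 1, d1 = 1, d2 = 1, alpha1 = 0.1, alpha2 = 0.4)

.baseSchedule <- function() disturbanceSchedule(50, "b1", 4)

.scenarioTable <- list(
  fig3b = function() list(
    network  = .basePlant(),
    schedule = .baseSchedule(),
    description = "open-loop plant alone; the b1 step shifts both outputs"),
  fig4a = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10)),
    schedule = .baseSchedule(),
    description = "ratio regulator; Y1*/Y2* = k2/k1 = 2 holds across the disturbance"),
  fig4b = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("LC", k1 = 1, k2 = 3, k3 = 2, eta = 10,
                                       theta1 = 4, theta2 = 5)),
    schedule = .baseSchedule(),
    description = "linear-combination regulator; Y1* - 3*Y2* = 1 holds"),
  fig5a = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("D1", k1 = 2.5, k2 = 0.5, k3 = 2, k4 = 2,
                                       eta1 = 10, eta2 = 10,
                                       theta1 = 1.5, theta2 = 0.5)),
    schedule = .baseSchedule(),
    description = "decoupling regulator I; (Y1*, Y2*) = (0.6, 1) nM"),
  fig5b = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("D2", k1 = 1, k2 = 0.8, k3 = 0.5, k4 = 0.5,
                                       eta1 = 0.5, eta2 = 0.5,
                                       theta1 = 10, theta2 = 8)),
    schedule = .baseSchedule(),
    description = "decoupling regulator II; (Y1*, Y2*) = (10, 10) nM"),
  fig5c = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("D3", k1 = 0.5, k2 = 2, k3 = 0.5, k4 = 2,
                                       eta1 = 0.5, eta2 = 10, theta1 = 8)),
    schedule = .baseSchedule(),
    description = "decoupling regulator III; (Y1*, Y2*) = (16, 4) nM"),
  fig6 = function() list(
    network  = closeLoop(.basePlant(),
                         regulatorSpec("D2_MISPAIRED",
                                       k1 = 1, k2 = 0.8, k3 = 0.5, k4 = 0.5,
                                       eta1 = 0.5, eta2 = 0.5,
                                       theta1 = 10, theta2 = 8)),
    schedule = .baseSchedule(),
    description = "mispaired decoupling regulator II; unstable closed loop")
)

#' List registered scenarios
#'
#' @return Character vector of scenario ids (named after the figure each
#'   reproduces).
#' @export
listScenarios <- function() names(.scenarioTable)

#' Materialize a registered study case
#'
#' Returns the fully parameterized network and its disturbance schedule
#' for one of the registered scenario ids (see [listScenarios()]). All
#' rate constants are the case's reference values; every
#' scenario applies the same step disturbance (b1 from 2 to 4 nM/min at
#' t = 50 min).
#'
#' @param id Scenario id, e.g. `"fig4a"`.
#' @return List with elements `network` ([ReactionNetwork-class] or
#'   [ClosedLoopNetwork-class]), `schedule`
#'   ([DisturbanceSchedule-class]) and `description`.
#' @examples
#' sc <- scenario("fig5a")
#' sc$network
#' @export
scenario <- function(id) {
  if (!id %in% names(.scenarioTable))
    stop("unknown scenario '", id, "'; available: ",
         paste(names(.scenarioTable), collapse = ", "), call. = FALSE)
  .scenarioTable[[id]]()
}
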