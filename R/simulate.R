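#' @include scenarios.R
NULL

## Memory variables per family: named linear combinations of controller
## species whose time derivative equals the control error, so that the
## combination integrates the error (the "hidden" integral action).
.memoryDefs <- function(family) {
  switch(family,
    R = ,
    R_PRODUCT = ,
    LC = list("Z1-Z2" = c(Z1 = 1, Z2 = -1)),
    D1 = ,
    D2 = list("Z3-Z1" = c(Z3 = 1, Z1 = -1),
              "Z4-Z2" = c(Z4 = 1, Z2 = -1)),
    D2_MISPAIRED = list("Z4-Z1" = c(Z4 = 1, Z1 = -1),
                        "Z3-Z2" = c(Z3 = 1, Z2 = -1)),
    D3 = list("Z3-Z1"   = c(Z3 = 1, Z1 = -1),
              "Z3+C-Z2" = c(Z3 = 1, C = 1, Z2 = -1)),
    stop("unknown regulator family: ", family, call. = FALSE)
  )
}

#' Simulate a network under timed disturbances
#'
#' Integrates the deterministic rate equations with a stiff-capable
#' solver (lsoda), restarting at each disturbance event: the named rate
#' constant is stepped to its new value and integration resumes from the
#' current state. Steady state is declared when, over the trailing
#' window, every species' relative drift and the right-hand-side
#' residual both fall below tolerance. Entries marginally below zero
#' (integrator noise) are clipped to 0 and counted.
#'
#' @param net A [ReactionNetwork-class] or [ClosedLoopNetwork-class].
#' @param tEnd Simulation horizon (min); must exceed the last event time.
#' @param schedule A [DisturbanceSchedule-class]; default empty.
#' @param initial Named numeric initial concentrations (nM); defaults to
#'   the network's, which are 0 for all built-in scenarios.
#' @param dt Output grid spacing (min).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param windowFrac Trailing fraction of the horizon used for the
#'   steady-state snapshot and drift check.
#' @param driftTol Relative drift tolerance over the trailing window.
#' @param residTol Tolerance on the max-norm of the right-hand side at
#'   the final state (nM/min).
#' @return A [SimulationResult-class]. Non-convergence by `tEnd` is
#'   reported through `converged = FALSE`, not an error; an integrator
#'   failure (e.g. a diverging unstable loop) is likewise reported with a
#'   diagnostic note and the trajectory up to the failure.
#' @examples
#' sc <- scenario("fig4a")
#' res <- simulateNetwork(sc$network, tEnd = 200, schedule = sc$schedule)
#' res@steadyState[c("Y1", "Y2")]
#' @export
simulateNetwork <- function(net, tEnd = 500, schedule = disturbanceSchedule(),
                            initial = NULL, dt = 0.1,
                            rtol = 1e-8, atol = 1e-10,
                            windowFrac = 0.05, driftTol = 1e-6,
                            residTol = 1e-8) {
  validObject(net)
  validObject(schedule)
  ev <- schedule@events
  if (nrow(ev)) {
    if (tEnd <= max(ev$time))
      stop("tEnd (", tEnd, ") must exceed the last event time (",
           max(ev$time), ")", call. = FALSE)
    bad <- setdiff(ev$parameter, names(net@parameters))
    if (length(bad))
      stop("schedule names unknown rate constants: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  state <- initialState(net)
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), net@species)
    if (length(bad))
      stop("unknown species in 'initial': ", paste(bad, collapse = ", "),
           call. = FALSE)
    state[names(initial)] <- initial
  }
  if (any(state < 0)) stop("initial concentrations must be >= 0", call. = FALSE)

  rhs <- odeRHS(net)
  derivFun <- function(t, y, p) list(unname(rhs(pmax(y, 0), p)))

  params <- net@parameters
  bounds <- c(0, ev$time, tEnd)
  allTimes <- NULL
  allTraj <- NULL
  notes <- character()
  aborted <- FALSE

  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    segTimes <- unique(c(seq(t0, t1, by = dt), t1))
    out <- tryCatch(
      deSolve::ode(y = state, times = segTimes, func = derivFun,
                   parms = params, method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = 50000),
      warning = function(w) {
        suppressWarnings(
          deSolve::ode(y = state, times = segTimes, func = derivFun,
                       parms = params, method = "lsoda",
                       rtol = rtol, atol = atol, maxsteps = 50000))
      },
      error = function(e) e)
    if (inherits(out, "error")) {
      notes <- c(notes, paste0("integration failed at t ~ ", t0, "-", t1,
                               " from state [",
                               paste(sprintf("%.4g", state), collapse = ", "),
                               "]: ", conditionMessage(out)))
      aborted <- TRUE
      break
    }
    out <- as.matrix(out)
    if (nrow(out) < length(segTimes)) {
      notes <- c(notes, sprintf(
        "integrator stopped early at t = %.4g (state [%s]); likely divergence",
        out[nrow(out), 1],
        paste(sprintf("%.4g", out[nrow(out), -1]), collapse = ", ")))
      aborted <- TRUE
    }
    keep <- if (seg == 1L) seq_len(nrow(out)) else -1L
    allTimes <- c(allTimes, out[keep, 1])
    allTraj <- rbind(allTraj, out[keep, -1, drop = FALSE])
    state <- setNames(out[nrow(out), -1], net@species)
    if (aborted) break
    if (seg <= nrow(ev))
      params[[ev$parameter[seg]]] <- ev$value[seg]
  }
  colnames(allTraj) <- net@species

  # clip integrator noise below zero
  neg <- allTraj < 0
  nClipped <- sum(neg)
  if (nClipped) {
    worst <- min(allTraj[neg])
    if (worst < -1e-6)
      notes <- c(notes, sprintf(
        "trajectory dipped to %.3g nM before clipping; inspect tolerances", worst))
    allTraj[neg] <- 0
  }

  n <- length(allTimes)
  winStart <- allTimes[n] - windowFrac * (allTimes[n] - allTimes[1])
  win <- allTimes >= winStart
  ss <- colMeans(allTraj[win, , drop = FALSE])
  finalState <- pmax(allTraj[n, ], 0)
  resid <- max(abs(rhs(finalState, params)))
  drift <- vapply(seq_len(ncol(allTraj)), function(j) {
    v <- allTraj[win, j]
    (max(v) - min(v)) / max(abs(mean(v)), 1e-6)
  }, numeric(1))
  converged <- !aborted && all(drift < driftTol) && resid < residTol
  if (!converged && !aborted)
    notes <- c(notes, sprintf(
      "not converged by t = %.4g: max drift %.3g, |rhs|_inf %.3g",
      tEnd, max(drift), resid))

  res <- new("SimulationResult",
    times = as.numeric(allTimes), trajectories = allTraj,
    steadyState = ss, converged = converged, residual = resid,
    memoryTraces = list(), finalParameters = params,
    clipped = as.numeric(nClipped), notes = notes)
  if (is(net, "ClosedLoopNetwork"))
    res@memoryTraces <- memoryTrace(res, net@regulator)
  res
}

#' Memory-variable traces of a simulation
#'
#' Evaluates the regulator family's memory variables along the
#' trajectory: `Z1 - Z2` for the ratio/product/linear-combination
#' families, `(Z3 - Z1, Z4 - Z2)` for decoupling regulators I/II, and
#' `(Z3 - Z1, Z3 + C - Z2)` for decoupling regulator III. Each is a
#' non-physical quantity whose derivative is the control error, so its
#' trace is the accumulated (integrated) error.
#'
#' @param result A [SimulationResult-class] from a closed loop of the
#'   given family.
#' @param spec The [RegulatorSpec-class] of that loop.
#' @return Named list of numeric series on the result's time grid (nM).
#' @export
memoryTrace <- function(result, spec) {
  defs <- .memoryDefs(spec@family)
  traj <- result@trajectories
  lapply(defs, function(w) {
    missing <- setdiff(names(w), colnames(traj))
    if (length(missing))
      stop("trajectories lack controller species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    as.vector(traj[, names(w), drop = FALSE] %*% w)
  })
}
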