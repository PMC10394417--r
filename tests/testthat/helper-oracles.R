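# Hand-coded right-hand sides for every closed loop used in the suite,
# written directly from the motif rate equations (independently of the
# package's stoichiometry/rate machinery), plus a per-session cache of
# scenario simulations so multiple test files can reuse one run.

basePlantParams <- c(b1 = 2, b2 = 1, d1 = 1, d2 = 1, alpha1 = 0.1, alpha2 = 0.4)

oraclePlantRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]])
}

oracleRClosedRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]] -
         p[["k3"]] * y[["Y2"]] * y[["Z2"]],
    Z1 = p[["k1"]] * y[["Y1"]] - p[["eta"]] * y[["Z1"]] * y[["Z2"]],
    Z2 = p[["k2"]] * y[["Y2"]] - p[["eta"]] * y[["Z1"]] * y[["Z2"]])
}

oracleLCClosedRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]] -
         p[["k3"]] * y[["Y2"]] * y[["Z2"]],
    Z1 = p[["theta1"]] + p[["k1"]] * y[["Y1"]] -
         p[["eta"]] * y[["Z1"]] * y[["Z2"]],
    Z2 = p[["theta2"]] + p[["k2"]] * y[["Y2"]] -
         p[["eta"]] * y[["Z1"]] * y[["Z2"]])
}

oracleD1ClosedRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]] -
         p[["k3"]] * y[["Y1"]] * y[["Z1"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]] -
         p[["k4"]] * y[["Y2"]] * y[["Z2"]],
    Z1 = p[["k1"]] * y[["Y1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    Z2 = p[["k2"]] * y[["Y2"]] - p[["eta2"]] * y[["Z2"]] * y[["Z4"]],
    Z3 = p[["theta1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    Z4 = p[["theta2"]] - p[["eta2"]] * y[["Z2"]] * y[["Z4"]])
}

oracleD2ClosedRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]] +
         p[["k3"]] * y[["Z3"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]] +
         p[["k4"]] * y[["Z4"]],
    Z1 = p[["k1"]] * y[["Y1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    Z2 = p[["k2"]] * y[["Y2"]] - p[["eta2"]] * y[["Z2"]] * y[["Z4"]],
    Z3 = p[["theta1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    Z4 = p[["theta2"]] - p[["eta2"]] * y[["Z2"]] * y[["Z4"]])
}

oracleD3ClosedRHS <- function(y, p) {
  c(Y1 = p[["b1"]] - p[["d1"]] * y[["Y1"]] + p[["alpha1"]] * y[["Y2"]] +
         p[["k3"]] * y[["Z3"]],
    Y2 = p[["b2"]] - p[["d2"]] * y[["Y2"]] + p[["alpha2"]] * y[["Y1"]] -
         p[["k4"]] * y[["Y2"]] * y[["Z2"]],
    Z1 = p[["k1"]] * y[["Y1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    Z2 = p[["k2"]] * y[["Y2"]] - p[["eta2"]] * y[["Z2"]] * y[["C"]],
    Z3 = p[["theta1"]] - p[["eta1"]] * y[["Z1"]] * y[["Z3"]],
    C  = p[["eta1"]] * y[["Z1"]] * y[["Z3"]] -
         p[["eta2"]] * y[["Z2"]] * y[["C"]])
}

closedLoopOracles <- list(
  fig4a = oracleRClosedRHS,
  fig4b = oracleLCClosedRHS,
  fig5a = oracleD1ClosedRHS,
  fig5b = oracleD2ClosedRHS,
  fig5c = oracleD3ClosedRHS
)

# random non-negative states for property checks, reproducible
randomStates <- function(n, nsp, scale = 5, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) stats::runif(nsp, 0, scale))
}

.runCache <- new.env(parent = emptyenv())

# simulate a registered scenario (with its disturbance schedule unless
# disturbed = FALSE) once per session and cache the result
cachedRun <- function(id, disturbed = TRUE, tEnd = 500) {
  key <- paste(id, disturbed, tEnd, sep = "|")
  if (!is.null(.runCache[[key]])) return(.runCache[[key]])
  sc <- scenario(id)
  sched <- if (disturbed) sc$schedule else disturbanceSchedule()
  res <- simulateNetwork(sc$network, tEnd = tEnd, schedule = sched)
  .runCache[[key]] <- res
  res
}

# fine-grid run for quadrature-identity checks (trapezoid error ~ dt^2)
fineRun <- function(id, tEnd = 80, dt = 0.01) {
  key <- paste("fine", id, tEnd, dt, sep = "|")
  if (!is.null(.runCache[[key]])) return(.runCache[[key]])
  sc <- scenario(id)
  res <- simulateNetwork(sc$network, tEnd = tEnd, schedule = sc$schedule,
                         dt = dt)
  .runCache[[key]] <- res
  res
}

# trapezoidal quadrature on a grid
trapz <- function(t, v) sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
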