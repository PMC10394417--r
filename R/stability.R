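#' @include simulate.R
NULL

## Closed-form equilibrium for the D2-family closed on the standard
## mutual-activation plant. The steady state is unique: the annihilation
## fluxes pin the outputs (eta*Zi*Zj = theta = k*Y), the plant equations
## then fix the actuator species, and the sensor species follow. Returns
## NULL when any component is non-positive (no positive equilibrium) or
## when the network does not have the expected structure.
.d2FamilyEquilibrium <- function(net) {
  if (!is(net, "ClosedLoopNetwork")) return(NULL)
  fam <- net@regulator@family
  if (!fam %in% c("D2", "D2_MISPAIRED")) return(NULL)
  p <- net@parameters
  need <- c("b1", "b2", "d1", "d2", "alpha1", "alpha2",
            "k1", "k2", "k3", "k4", "eta1", "eta2", "theta1", "theta2")
  if (!all(need %in% names(p))) return(NULL)
  if (net@regulator@degradationRate > 0) return(NULL)
  mis <- fam == "D2_MISPAIRED"
  y1 <- if (mis) p[["theta2"]] / p[["k1"]] else p[["theta1"]] / p[["k1"]]
  y2 <- if (mis) p[["theta1"]] / p[["k2"]] else p[["theta2"]] / p[["k2"]]
  z3 <- (p[["d1"]] * y1 - p[["alpha1"]] * y2 - p[["b1"]]) / p[["k3"]]
  z4 <- (p[["d2"]] * y2 - p[["alpha2"]] * y1 - p[["b2"]]) / p[["k4"]]
  if (z3 <= 0 || z4 <= 0) return(NULL)
  if (mis) {
    z1 <- p[["theta2"]] / (p[["eta1"]] * z4)
    z2 <- p[["theta1"]] / (p[["eta2"]] * z3)
  } else {
    z1 <- p[["theta1"]] / (p[["eta1"]] * z3)
    z2 <- p[["theta2"]] / (p[["eta2"]] * z4)
  }
  eq <- setNames(numeric(length(net@species)), net@species)
  eq[net@targetMap[["Y1"]]] <- y1
  eq[net@targetMap[["Y2"]]] <- y2
  eq[c("Z1", "Z2", "Z3", "Z4")] <- c(z1, z2, z3, z4)
  if (any(eq <= 0)) return(NULL)
  eq
}

.newtonRoot <- function(rhs, jac, seed, tol = 1e-9, maxIter = 200) {
  x <- seed
  f <- rhs(pmax(x, 0))
  for (it in seq_len(maxIter)) {
    if (max(abs(f)) <= tol) break
    J <- jac(pmax(x, 0))
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- tryCatch(rhs(pmax(xn, 0)), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(f)) || lam < 1e-6)) break
      lam <- lam / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) > tol) return(NULL)
  x
}

#' Locate a non-negative equilibrium of a network
#'
#' Damped Newton iteration on the mass-action right-hand side using the
#' exact analytic Jacobian. Tried from the supplied seed and, failing
#' that, from a short simulation endpoint and a ladder of constant
#' states. Roots with any meaningfully negative component are refused
#' (tiny negative round-off is clipped to 0).
#'
#' @param net A [ReactionNetwork-class].
#' @param seed Optional named/ordered numeric seed state (nM).
#' @param tol Residual tolerance: the returned root satisfies
#'   `max(abs(rhs))` <= `tol` (nM/min).
#' @return Named numeric equilibrium vector (nM).
#' @export
findEquilibrium <- function(net, seed = NULL, tol = 1e-9) {
  validObject(net)
  rhsFun <- odeRHS(net)
  f <- function(x) unname(rhsFun(x))
  jac <- function(x) jacobianMatrix(net, x)
  n <- length(net@species)

  seeds <- list()
  if (!is.null(seed)) seeds <- c(seeds, list(.orderState(net, seed)))
  an <- .d2FamilyEquilibrium(net)
  if (!is.null(an)) seeds <- c(seeds, list(unname(an)))
  simSeed <- tryCatch({
    res <- simulateNetwork(net, tEnd = 200, dt = 0.5)
    st <- res@trajectories[nrow(res@trajectories), ]
    if (all(is.finite(st)) && max(st) < 1e6) unname(st) else NULL
  }, error = function(e) NULL)
  if (!is.null(simSeed)) seeds <- c(seeds, list(simSeed))
  seeds <- c(seeds, list(rep(1, n), rep(0.1, n), rep(10, n),
                         rep(0, n)))

  for (s in seeds) {
    root <- .newtonRoot(f, jac, s, tol = tol)
    if (is.null(root)) next
    if (any(root < -1e-6)) next       # refuse negative equilibria
    root <- pmax(root, 0)
    if (max(abs(f(root))) <= max(tol, 1e-8)) return(setNames(root, net@species))
  }
  stop("no non-negative equilibrium found from any seed; ",
       "consider supplying the endpoint of a long simulation as 'seed'",
       call. = FALSE)
}

.charPolyFromEigen <- function(ev) {
  coef <- 1
  for (lam in ev) coef <- c(coef, 0) - c(0, coef * lam)
  # imaginary parts cancel for a real matrix; only round-off remains
  Re(coef)
}

#' Routh-Hurwitz stability test
#'
#' Builds the Routh array from the coefficients of a real polynomial
#' (descending powers, leading coefficient > 0 after normalization). All
#' first-column entries positive means every root has negative real part
#' (`"stable"`); any sign change means a right-half-plane root
#' (`"unstable"`); an exact zero in the first column is reported as
#' `"marginal"` — no epsilon perturbation is applied. A negative
#' coefficient short-circuits to `"unstable"` (positivity of all
#' coefficients is necessary for Hurwitz stability).
#'
#' @param coefficients Numeric coefficients, descending powers, length
#'   >= 2 (degree >= 1).
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @examples
#' routhHurwitz(c(1, 3, 3, 1))   # (s+1)^3 -> stable
#' routhHurwitz(c(1, 0, -1))     # s^2 - 1 -> unstable
#' @export
routhHurwitz <- function(coefficients) {
  a <- as.numeric(coefficients)
  if (length(a) < 2L) stop("need a polynomial of degree >= 1", call. = FALSE)
  if (a[1] == 0) stop("leading coefficient must be nonzero", call. = FALSE)
  if (a[1] < 0) a <- -a
  n <- length(a) - 1L                 # degree
  scale <- max(abs(a))
  zeroTol <- 1e-12 * scale
  # all roots in the open left half-plane forces strictly positive
  # coefficients, so any negative coefficient certifies a RHP root
  if (any(a < -zeroTol)) return("unstable")
  width <- ceiling((n + 1L) / 2)
  rows <- matrix(0, nrow = n + 1L, ncol = width + 1L)
  r1 <- a[seq(1, n + 1L, by = 2)]
  r2 <- a[seq(2, n + 1L, by = 2)]
  rows[1, seq_along(r1)] <- r1
  if (length(r2)) rows[2, seq_along(r2)] <- r2
  for (i in seq(3, n + 1L)) {
    if (n < 2L) break
    piv <- rows[i - 1L, 1L]
    if (abs(piv) <= zeroTol) return("marginal")
    for (j in seq_len(width)) {
      rows[i, j] <- (piv * rows[i - 2L, j + 1L] -
                     rows[i - 2L, 1L] * rows[i - 1L, j + 1L]) / piv
    }
  }
  firstCol <- rows[seq_len(n + 1L), 1L]
  if (any(abs(firstCol) <= zeroTol)) return("marginal")
  if (all(firstCol > 0)) "stable" else "unstable"
}

.eigenVerdict <- function(ev, marginTol = 1e-9) {
  re <- Re(ev)
  if (any(re > marginTol)) "unstable"
  else if (all(re < -marginTol)) "stable"
  else "marginal"
}

#' Assess local stability of an equilibrium
#'
#' Locates an equilibrium (Newton from the supplied or default seeds),
#' linearizes the mass-action dynamics there, and classifies the
#' equilibrium. Jacobian eigenvalues are the authoritative test; the
#' Routh-Hurwitz verdict on the characteristic polynomial (assembled from
#' the eigenvalues, never by determinant expansion) serves as an
#' independent algebraic cross-check. A decisive disagreement between the
#' two is a hard error, flagging numerical pathology.
#'
#' @param net A [ReactionNetwork-class] (typically a closed loop).
#' @param seed Optional equilibrium seed passed to [findEquilibrium()].
#' @param marginTol Eigenvalue real parts within `c(-marginTol, marginTol)`
#'   are reported as marginal, never coerced to a side.
#' @return A [StabilityReport-class].
#' @examples
#' rep <- assessStability(scenario("fig4a")$network)
#' rep@verdict
#' @export
assessStability <- function(net, seed = NULL, marginTol = 1e-9) {
  eq <- findEquilibrium(net, seed = seed)
  J <- jacobianMatrix(net, eq)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  cp <- .charPolyFromEigen(ev)
  rh <- routhHurwitz(cp)
  verdict <- .eigenVerdict(ev, marginTol)
  notes <- character()
  if (verdict != rh) {
    if (verdict == "marginal" || rh == "marginal") {
      notes <- c(notes, sprintf(
        "eigenvalue verdict '%s' vs Routh-Hurwitz '%s'; eigenvalues are authoritative",
        verdict, rh))
    } else {
      stop("eigenvalue test says '", verdict, "' but Routh-Hurwitz says '",
           rh, "': numerical pathology, refusing to report", call. = FALSE)
    }
  }
  new("StabilityReport", equilibrium = eq, eigenvalues = ev,
      charPoly = cp, verdict = verdict, notes = notes)
}

#' Scan controller parameter space for stabilizing points
#'
#' Evaluates closed-loop stability of a regulator family over a
#' log-spaced grid of its rate constants on a fixed plant. The default
#' grid places `pointsPerDecade` values per decade in `[lower, upper]`
#' for each scanned parameter; the full factorial is subsampled to at
#' most `maxPoints` combinations by a fixed stride (deterministic, no
#' seeds). Used to reproduce the infeasibility of the mispaired
#' decoupling-II configuration: no scanned point stabilizes it, while the
#' correctly paired architecture is stable at its reference parameters.
#'
#' @param plant A plant [ReactionNetwork-class] with two outputs.
#' @param spec A [RegulatorSpec-class] template; scanned parameters are
#'   overwritten point by point, the rest keep the template values.
#' @param parameters Character vector of rate constants to scan
#'   (default: all of the family's).
#' @param lower,upper Grid range for every scanned parameter.
#' @param pointsPerDecade Grid density.
#' @param maxPoints Cap on the number of evaluated combinations.
#' @return List with `points` (data.frame: one column per scanned
#'   parameter, plus `verdict` — `"stable"`, `"unstable"`, `"marginal"`
#'   or `"no_equilibrium"`) and `fractionStable`.
#' @export
pairingScan <- function(plant, spec, parameters = names(spec@parameters),
                        lower = 0.01, upper = 100,
                        pointsPerDecade = 4, maxPoints = 1e4) {
  validObject(spec)
  net <- closeLoop(plant, spec)
  vals <- 10^seq(log10(lower), log10(upper), by = 1 / pointsPerDecade)
  nv <- length(vals)
  np <- length(parameters)
  total <- nv^np
  nPts <- min(maxPoints, total)
  stride <- max(1, floor(total / nPts))
  if (stride > 1 && stride %% nv == 0) stride <- stride - 1
  idx0 <- (seq_len(nPts) - 1) * stride

  useAnalytic <- spec@family %in% c("D2", "D2_MISPAIRED")
  grid <- matrix(0, nrow = nPts, ncol = np, dimnames = list(NULL, parameters))
  verdict <- character(nPts)
  p0 <- net@parameters
  for (i in seq_len(nPts)) {
    rem <- idx0[i]
    digits <- integer(np)
    for (d in seq_len(np)) {
      digits[d] <- rem %% nv
      rem <- (rem - digits[d]) / nv
    }
    pv <- vals[digits + 1L]
    grid[i, ] <- pv
    p <- p0
    p[parameters] <- pv
    net@parameters <- p
    eq <- if (useAnalytic) .d2FamilyEquilibrium(net) else
      tryCatch(findEquilibrium(net), error = function(e) NULL)
    if (is.null(eq)) {
      verdict[i] <- "no_equilibrium"
      next
    }
    J <- jacobianMatrix(net, eq)
    ev <- eigen(J, only.values = TRUE)$values
    verdict[i] <- .eigenVerdict(ev)
  }
  pts <- as.data.frame(grid)
  pts$verdict <- verdict
  list(points = pts, fractionStable = mean(verdict == "stable"))
}

#' Positive-real balance residual of the augmented R/LC controller block
#'
#' For the ratio or linear-combination regulator carrying inhibitory
#' actuation on both outputs (the `extraInhibition` augmentation, rate
#' `k4`), the controller block around an equilibrium is a positive-real
#' system exactly when `k2*k4*Z1* = k1*k3*Z2*`. This returns the residual
#' `k2*k4*Z1* - k1*k3*Z2*`; a zero residual flags the PR-certifiable
#' configuration. No stability conclusion is drawn from the residual
#' alone.
#'
#' @param net A [ClosedLoopNetwork-class] of family R or LC with
#'   `extraInhibition = TRUE`.
#' @param equilibrium Optional equilibrium; located via
#'   [findEquilibrium()] when omitted.
#' @return Numeric residual (nM/min scale).
#' @export
prBalanceCheck <- function(net, equilibrium = NULL) {
  if (!is(net, "ClosedLoopNetwork") ||
      !net@regulator@family %in% c("R", "LC") ||
      !net@regulator@extraInhibition)
    stop("requires a closed loop of family R or LC with extraInhibition",
         call. = FALSE)
  if (is.null(equilibrium)) equilibrium <- findEquilibrium(net)
  p <- net@parameters
  unname(p[["k2"]] * p[["k4"]] * equilibrium[["Z1"]] -
         p[["k1"]] * p[["k3"]] * equilibrium[["Z2"]])
}
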