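test_that("plant equilibrium from the root finder matches the closed form", {
  net <- scenario("fig3b")$network
  eq <- findEquilibrium(net)
  expect_equal(eq, plantSteadyState(2, 1, 1, 1, 0.1, 0.4), tolerance = 1e-9)
})

test_that("a network with no input has the origin as equilibrium", {
  net <- reactionNetwork(
    species = c("A", "B"),
    reactions = list(reaction("A", c("A", "B"), "k"),
                     reaction("A", NULL, "d"), reaction("B", NULL, "d")),
    parameters = c(k = 1, d = 2))
  eq <- findEquilibrium(net, seed = c(A = 0, B = 0))
  expect_equal(eq, c(A = 0, B = 0))
})

test_that("plant Jacobian is the constant coupling matrix", {
  net <- scenario("fig3b")$network
  for (st in randomStates(3, 2, seed = 2)) {
    J <- jacobianMatrix(net, setNames(st, c("Y1", "Y2")))
    expect_equal(J, matrix(c(-1, 0.4, 0.1, -1), 2, 2,
                           dimnames = list(c("Y1", "Y2"), c("Y1", "Y2"))))
  }
})

test_that("ratio-regulator Jacobian rows match hand differentiation", {
  net <- scenario("fig4a")$network
  eq <- findEquilibrium(net)
  J <- jacobianMatrix(net, eq)
  p <- rateConstants(net)
  # d(Z1dot)/d(state): Z1dot = k1 Y1 - eta Z1 Z2
  expect_equal(J["Z1", ],
               c(Y1 = p[["k1"]], Y2 = 0,
                 Z1 = -p[["eta"]] * eq[["Z2"]],
                 Z2 = -p[["eta"]] * eq[["Z1"]]))
})

test_that("analytic Jacobian agrees with central finite differences", {
  h <- 1e-6
  for (id in c("fig3b", "fig4a", "fig4b", "fig5a", "fig5b", "fig5c", "fig6")) {
    net <- scenario(id)$network
    rhs <- odeRHS(net)
    spn <- speciesNames(net)
    for (st in randomStates(4, length(spn), seed = 13)) {
      st <- setNames(st + 0.5, spn)   # interior states
      J <- jacobianMatrix(net, st)
      for (j in seq_along(st)) {
        up <- st; up[j] <- up[j] + h
        dn <- st; dn[j] <- dn[j] - h
        fd <- (rhs(up) - rhs(dn)) / (2 * h)
        expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
      }
    }
  }
})

test_that("Routh-Hurwitz verdicts on elementary polynomials", {
  expect_identical(routhHurwitz(c(1, 1)), "stable")        # s + 1
  expect_identical(routhHurwitz(c(1, 0, -1)), "unstable")  # s^2 - 1
  expect_identical(routhHurwitz(c(1, 0, 1)), "marginal")   # s^2 + 1
  # plant characteristic polynomial s^2 + (d1+d2) s + (d1 d2 - a1 a2):
  # stable exactly because d1 d2 > a1 a2 (1 > 0.04)
  expect_identical(routhHurwitz(c(1, 2, 0.96)), "stable")
  expect_error(routhHurwitz(1), "degree")
})

test_that("Routh-Hurwitz agrees with root construction on random polynomials", {
  set.seed(99)
  for (i in seq_len(1000)) {
    n <- sample(2:7, 1)
    # build roots: real and conjugate pairs with known real-part signs
    nPairs <- sample(0:(n %/% 2), 1)
    nReal <- n - 2 * nPairs
    re <- c(runif(nPairs, -3, 3), runif(nReal, -3, 3))
    im <- c(runif(nPairs, 0.1, 3), rep(0, nReal))
    pairRe <- re[seq_len(nPairs)]
    realRe <- if (nPairs) re[-seq_len(nPairs)] else re
    roots <- complex(real = rep(pairRe, each = 2),
                     imaginary = c(rbind(im[seq_len(nPairs)],
                                         -im[seq_len(nPairs)])))
    roots <- c(roots, complex(real = realRe, imaginary = 0))
    if (min(abs(Re(roots))) < 0.05) next   # stay away from the margin
    coef <- 1
    for (r in roots) coef <- c(coef, 0) - c(0, coef * r)
    coef <- Re(coef)
    truth <- if (all(Re(roots) < 0)) "stable" else "unstable"
    expect_identical(routhHurwitz(coef), truth,
                     info = paste("roots:", paste(round(roots, 3), collapse = " ")))
  }
})

test_that("stability assessment certifies the bundled closed loops", {
  for (id in c("fig4a", "fig4b", "fig5a", "fig5b", "fig5c")) {
    rep <- assessStability(scenario(id)$network)
    expect_identical(rep@verdict, "stable")
    # the equilibrium satisfies the root tolerance
    net <- scenario(id)$network
    expect_lt(max(abs(odeRHS(net)(rep@equilibrium))), 1e-8)
    # eigenvalue signs and Routh-Hurwitz agree
    expect_identical(routhHurwitz(rep@charPoly), "stable")
  }
})

test_that("the mispaired decoupling-II loop is unstable at its reference point", {
  rep <- assessStability(scenario("fig6")$network)
  expect_identical(rep@verdict, "unstable")
  expect_true(any(Re(rep@eigenvalues) > 0))
  expect_identical(routhHurwitz(rep@charPoly), "unstable")
})

test_that("simulation and root finding converge to the same equilibrium", {
  for (id in c("fig4a", "fig5a", "fig5c")) {
    sc <- scenario(id)
    res <- cachedRun(id)                     # with disturbance (b1 = 4)
    net <- sc$network
    rateConstants(net) <- c(b1 = 4)
    eq <- findEquilibrium(net, seed = res@steadyState)
    expect_equal(res@steadyState, eq, tolerance = 1e-6)
  }
})

test_that("mispairing scan finds no stabilizing parameters, correct pairing does", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  mis <- scenario("fig6")$network@regulator
  scan <- pairingScan(plant, mis, maxPoints = 500)
  expect_identical(nrow(scan$points), 500L)
  expect_identical(scan$fractionStable, 0)
  expect_false(any(scan$points$verdict == "stable"))
  # single-point scan at the reference decoupling-II values == assessStability
  d2 <- scenario("fig5b")$network@regulator
  one <- pairingScan(plant, d2, parameters = "k1", lower = d2@parameters[["k1"]],
                     upper = d2@parameters[["k1"]], maxPoints = 1)
  expect_identical(one$points$verdict, "stable")
  expect_identical(one$fractionStable, 1)
})

test_that("positive-real balance residual behaves as an antisymmetric form", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  spec <- regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10, k4 = 0.8,
                        extraInhibition = TRUE)
  cl <- closeLoop(plant, spec)
  eq <- findEquilibrium(cl)
  res <- prBalanceCheck(cl, eq)
  p <- rateConstants(cl)
  expect_equal(res, p[["k2"]] * p[["k4"]] * eq[["Z1"]] -
                    p[["k1"]] * p[["k3"]] * eq[["Z2"]])
  # symmetric rates with a symmetric equilibrium give residual zero, and the
  # residual flips sign under swapping (k1,k3) <-> (k2,k4) with Z1* <-> Z2*
  eqSym <- eq; eqSym[c("Z1", "Z2")] <- 1
  specSym <- regulatorSpec("R", k1 = 1, k2 = 1, k3 = 2, eta = 10, k4 = 2,
                           extraInhibition = TRUE)
  clSym <- closeLoop(plant, specSym)
  expect_equal(prBalanceCheck(clSym, eqSym), 0)
  eqSwap <- eq; eqSwap[c("Z1", "Z2")] <- eq[c("Z2", "Z1")]
  specSwap <- regulatorSpec("R", k1 = 1, k2 = 0.5, k3 = 0.8, eta = 10, k4 = 2,
                            extraInhibition = TRUE)
  clSwap <- closeLoop(plant, specSwap)
  expect_equal(prBalanceCheck(clSwap, eqSwap), -res)
  # wrong family refused
  expect_error(prBalanceCheck(scenario("fig5a")$network), "extraInhibition")
})
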