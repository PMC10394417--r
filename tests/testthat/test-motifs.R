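test_that("plant factory builds the six birth-death/coupling reactions", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  expect_identical(speciesNames(plant), c("Y1", "Y2"))
  expect_identical(length(reactions(plant)), 6L)
  expect_identical(outputSpecies(plant), c("Y1", "Y2"))
  expect_error(makePlant(-2, 1, 1, 1, 0.1, 0.4), "positive")
})

test_that("plant closed-form steady state matches long-horizon integration", {
  # base parameters
  expect_equal(plantSteadyState(2, 1, 1, 1, 0.1, 0.4),
               c(Y1 = 2.1 / 0.96, Y2 = 1.8 / 0.96))
  # post-disturbance value
  expect_equal(plantSteadyState(4, 1, 1, 1, 0.1, 0.4),
               c(Y1 = 4.1 / 0.96, Y2 = 2.6 / 0.96))
  # decoupled limit: alpha -> 0 is outside the strictly positive domain of
  # the factory, but the formula limit Y1* = b1/d1 holds for tiny alpha
  expect_equal(unname(plantSteadyState(2, 1, 1, 1, 1e-12, 1e-12)[1]), 2,
               tolerance = 1e-9)
  # independent oracle: integrate the plant rate equations to t = 200
  res <- simulateNetwork(makePlant(2, 1, 1, 1, 0.1, 0.4), tEnd = 200)
  expect_true(res@converged)
  expect_equal(res@steadyState, plantSteadyState(2, 1, 1, 1, 0.1, 0.4),
               tolerance = 1e-7)
  # condition d1*d2 > alpha1*alpha2 is enforced
  expect_error(plantSteadyState(2, 1, 1, 1, 1, 1), "d1\\*d2")
})

test_that("regulator fragments have the defining species and reactions", {
  specs <- list(
    R  = list(spec = regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10),
              species = c("Z1", "Z2"), n = 4L),
    LC = list(spec = regulatorSpec("LC", k1 = 1, k2 = 3, k3 = 2, eta = 10,
                                   theta1 = 4, theta2 = 5),
              species = c("Z1", "Z2"), n = 6L),
    D1 = list(spec = regulatorSpec("D1", k1 = 2.5, k2 = 0.5, k3 = 2, k4 = 2,
                                   eta1 = 10, eta2 = 10, theta1 = 1.5,
                                   theta2 = 0.5),
              species = c("Z1", "Z2", "Z3", "Z4"), n = 8L),
    D3 = list(spec = regulatorSpec("D3", k1 = 0.5, k2 = 2, k3 = 0.5, k4 = 2,
                                   eta1 = 0.5, eta2 = 10, theta1 = 8),
              species = c("Z1", "Z2", "Z3", "C"), n = 7L))
  for (case in specs) {
    frag <- makeRegulator(case$spec)
    expect_identical(setdiff(speciesNames(frag), c("Y1", "Y2")), case$species)
    expect_identical(length(reactions(frag)), case$n)
  }
  # D3 includes the complex-consuming annihilation Z2 + C -> 0
  fragD3 <- makeRegulator(specs$D3$spec)
  kinds <- vapply(reactions(fragD3), function(rx)
    paste(sort(names(rx@reactants)), collapse = "+"), "")
  expect_true("C+Z2" %in% kinds)
  expect_error(makeRegulator(regulatorSpec("R", k1 = 1)), "requires")
})

test_that("mispaired decoupling-II swaps only the annihilation pairs", {
  spec <- regulatorSpec("D2_MISPAIRED", k1 = 1, k2 = 0.8, k3 = 0.5, k4 = 0.5,
                        eta1 = 0.5, eta2 = 0.5, theta1 = 10, theta2 = 8)
  frag <- makeRegulator(spec)
  pairs <- vapply(reactions(frag), function(rx)
    if (!length(rx@products) && length(rx@reactants) == 2L)
      paste(sort(names(rx@reactants)), collapse = "+") else "", "")
  expect_setequal(setdiff(pairs, ""), c("Z1+Z4", "Z2+Z3"))
})

test_that("loop closing merges species, binds targets and is order-independent", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  cl <- closeLoop(plant, regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10))
  expect_identical(speciesNames(cl), c("Y1", "Y2", "Z1", "Z2"))
  expect_identical(length(reactions(cl)), 10L)
  expect_identical(cl@targetMap, c(Y1 = "Y1", Y2 = "Y2"))

  clD1 <- closeLoop(plant, scenario("fig5a")$network@regulator)
  expect_identical(length(speciesNames(clD1)), 6L)

  # permuting the plant's reaction list leaves the rate equations unchanged
  plant2 <- plant
  plant2@reactions <- rev(plant@reactions)
  cl2 <- closeLoop(plant2, regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10))
  rhs1 <- odeRHS(cl); rhs2 <- odeRHS(cl2)
  for (st in randomStates(6, 4, seed = 3)) {
    st <- setNames(st, speciesNames(cl))
    expect_equal(rhs1(st), rhs2(st))
  }
})

test_that("colliding controller parameter names are namespaced", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  # rename a plant parameter to collide with the controller's k1
  plant@parameters <- c(k1 = 2, b2 = 1, d1 = 1, d2 = 1,
                        alpha1 = 0.1, alpha2 = 0.4)
  plant@reactions[[1]]@rate <- "k1"
  cl <- closeLoop(plant, regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10))
  expect_true("ctrl.k1" %in% names(rateConstants(cl)))
  expect_equal(rateConstants(cl)[["k1"]], 2)
  expect_equal(rateConstants(cl)[["ctrl.k1"]], 0.5)
})

test_that("predicted set-points follow the defining closed forms", {
  expect_equal(predictedSetpoint(
    regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10))$target,
    c(ratio = 2))
  expect_equal(predictedSetpoint(
    regulatorSpec("R_PRODUCT", k1 = 0.5, k2 = 0.5, k3 = 2, eta = 10))$target,
    c(product = 1))
  lc <- predictedSetpoint(
    regulatorSpec("LC", k1 = 1, k2 = 3, k3 = 2, eta = 10, theta1 = 4, theta2 = 5))
  expect_equal(lc$target, c(lincomb = 1))
  expect_equal(lc$weights, c(Y1 = 1, Y2 = -3))
  expect_equal(predictedSetpoint(
    regulatorSpec("D1", k1 = 2.5, k2 = 0.5, k3 = 2, k4 = 2, eta1 = 10,
                  eta2 = 10, theta1 = 1.5, theta2 = 0.5))$target,
    c(Y1 = 0.6, Y2 = 1))
  expect_equal(predictedSetpoint(
    regulatorSpec("D3", k1 = 0.5, k2 = 2, k3 = 0.5, k4 = 2, eta1 = 0.5,
                  eta2 = 10, theta1 = 8))$target,
    c(Y1 = 16, Y2 = 4))
})

test_that("decoupling I and II share controller dynamics but not closed-loop dynamics", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  params <- c(k1 = 1, k2 = 0.8, k3 = 0.5, k4 = 0.5, eta1 = 0.5, eta2 = 0.5,
              theta1 = 10, theta2 = 8)
  cl1 <- closeLoop(plant, regulatorSpec("D1", params))
  cl2 <- closeLoop(plant, regulatorSpec("D2", params))
  rhs1 <- odeRHS(cl1); rhs2 <- odeRHS(cl2)
  zrows <- c("Z1", "Z2", "Z3", "Z4")
  sawDifferentY <- FALSE
  for (st in randomStates(10, 6, seed = 11)) {
    st <- setNames(st, speciesNames(cl1))
    d1 <- rhs1(st); d2 <- rhs2(st)
    expect_equal(d1[zrows], d2[zrows], tolerance = 1e-14)
    if (max(abs(d1[c("Y1", "Y2")] - d2[c("Y1", "Y2")])) > 1e-8)
      sawDifferentY <- TRUE
  }
  expect_true(sawDifferentY)   # different actuation => different transients
})

test_that("extra inhibition on Y1 leaves the controller dynamics unchanged", {
  plant <- makePlant(2, 1, 1, 1, 0.1, 0.4)
  for (fam in c("R", "LC")) {
    base <- if (fam == "R")
      regulatorSpec("R", k1 = 0.5, k2 = 1, k3 = 2, eta = 10)
    else
      regulatorSpec("LC", k1 = 1, k2 = 3, k3 = 2, eta = 10,
                    theta1 = 4, theta2 = 5)
    aug <- base
    aug@extraInhibition <- TRUE
    aug@parameters <- c(aug@parameters, k4 = 1.5)
    cl0 <- closeLoop(plant, base)
    cl1 <- closeLoop(plant, aug)
    rhs0 <- odeRHS(cl0); rhs1 <- odeRHS(cl1)
    sawDifferentY1 <- FALSE
    for (st in randomStates(8, 4, seed = 5)) {
      st <- setNames(st, speciesNames(cl0))
      d0 <- rhs0(st); d1 <- rhs1(st)
      expect_equal(d0[c("Z1", "Z2")], d1[c("Z1", "Z2")], tolerance = 1e-14)
      if (abs(d0[["Y1"]] - d1[["Y1"]]) > 1e-8) sawDifferentY1 <- TRUE
    }
    expect_true(sawDifferentY1)  # the augmentation only alters the Y1 equation
  }
  expect_error(
    validObject(regulatorSpec("D1", k1 = 1, k2 = 1, k3 = 1, k4 = 1, eta1 = 1,
                              eta2 = 1, theta1 = 1, theta2 = 1,
                              extraInhibition = TRUE)),
    "only defined")
})

test_that("controller dilution appends one decay reaction per controller species", {
  spec <- regulatorSpec("D1", k1 = 2.5, k2 = 0.5, k3 = 2, k4 = 2, eta1 = 10,
                        eta2 = 10, theta1 = 1.5, theta2 = 0.5,
                        degradationRate = 0.01)
  frag <- makeRegulator(spec)
  decays <- Filter(function(rx) rx@rate == "delta", reactions(frag))
  expect_identical(length(decays), 4L)
  expect_equal(rateConstants(frag)[["delta"]], 0.01)
})
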