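test_that("the sequestration bound reproduces the design-table arithmetic", {
  expect_equal(etaBar(1, 1, 1.2875, 1.3920), 0.4334, tolerance = 1e-4)
  expect_equal(etaBar(1, 1, 0.5238, 0.3450), 10.5645, tolerance = 1e-4)
  expect_equal(etaBar(1, 1, 1.5816, 0.2626), 1.5233, tolerance = 1e-3)
  expect_equal(etaBar(1, 1, 0.2749, 0.0738), 179.3057, tolerance = 1e-4)
  expect_equal(etaBar(2, 1, 1, 1), 4)
  expect_true(is.na(etaBar(1, 1, 0, 6.2713)))   # no degradation: undefined
  expect_error(etaBar(1, 1, 1, 0), "positive")
  expect_error(etaBar(1, 1, 1, -2), "positive")
})

test_that("the bound is homogeneous of degree 4 in the controller gains", {
  set.seed(3)
  for (i in 1:10) {
    th1 <- runif(1, 0.1, 5); th2 <- runif(1, 0.1, 5)
    gP <- runif(1, 0.1, 3); mu <- runif(1, 0.05, 5); cc <- runif(1, 0.2, 4)
    expect_equal(etaBar(cc * th1, cc * th2, gP, mu),
                 cc^4 * etaBar(th1, th2, gP, mu), tolerance = 1e-12)
  }
})

test_that("closed-loop derivative implements the controller equations", {
  # abstract mode, eta = 0, gammaC = 0, theta1 = theta2 = gammaP = 1,
  # state (1, 1, 1), mu = 1: rates (0, 1, 1)
  loop <- abstractLoop(AIFParameters(eta = 0, theta1 = 1, theta2 = 1), 1, gammaP = 1)
  expect_equal(unname(closedLoopDerivative(loop, c(1, 1, 1), 0)), c(0, 1, 1))
  # the sequestration flux eta z1 z2 is shared exactly by both z rates
  loop2 <- abstractLoop(AIFParameters(eta = 2, theta1 = 1, theta2 = 1), 1, gammaP = 1)
  d0 <- closedLoopDerivative(loop, c(1, 1, 3), 0)
  d2 <- closedLoopDerivative(loop2, c(1, 1, 3), 0)
  expect_equal(unname(d0 - d2), c(0, 6, 6))   # eta z1 z2 = 2*1*3
  # controller degradation enters each z rate with its own concentration
  loop3 <- abstractLoop(AIFParameters(eta = 0, theta1 = 1, theta2 = 1,
                                      gammaC = 0.5), 1, gammaP = 1)
  d3 <- closedLoopDerivative(loop3, c(1, 2, 4), 0)
  expect_equal(unname(d3), c(2 - 1, 1 - 0.5 * 2, 1 - 0.5 * 4))
})

test_that("the embedded target keeps native degradation but gains actuation", {
  cl <- loadClock("AD2015")
  ref <- clockReference(cl)
  pert <- applyLossOfFunction(cl$model, "FRQ", "WC1")
  loop <- closedLoop(pert, "FRQ", AIFParameters(10, 2, 1, 0), ref,
                     plantInit = c(FRQ = 1, WC1 = 0.5, WCC = 1))
  st <- c(1, 0.5, 1, 0.3, 0.1)   # FRQ, WC1, WCC, z1, z2
  d <- closedLoopDerivative(loop, st, 5)
  dPlant <- ssDerivative(pert, st[1:3], 5)
  expect_equal(d[["FRQ"]], dPlant[["FRQ"]] + 2 * 0.3)  # theta1 * z1 added
  # no WC1 production input survives, native WCC-dependent degradation does
  st2 <- st; st2[2] <- 2
  expect_equal(closedLoopDerivative(loop, st2, 5)[["FRQ"]], d[["FRQ"]])
  st3 <- st; st3[3] <- 2
  expect_lt(closedLoopDerivative(loop, st3, 5)[["FRQ"]], d[["FRQ"]])
})

test_that("perfect adaptation: x1 -> mu/theta2 whatever the plant and gain", {
  for (gP in c(0.5, 1, 2)) for (th1 in c(1, 5)) {
    eta <- 100 * etaBar(th1, 1, gP, 2)
    loop <- abstractLoop(AIFParameters(eta, th1, 1, 0), 2, gammaP = gP)
    tr <- simulateClosedLoop(loop, c(0, 300), seq(0, 300, 2))
    expect_equal(unname(tail(trajValues(tr)[, "x1"], 1)), 2, tolerance = 1e-3)
  }
  # the sensing rate rescales the set point: theta2 = 2 halves the output
  loop <- abstractLoop(AIFParameters(100 * etaBar(1, 2, 1, 2), 1, 2, 0), 2, 1)
  tr <- simulateClosedLoop(loop, c(0, 300), seq(0, 300, 2))
  expect_equal(unname(tail(trajValues(tr)[, "x1"], 1)), 1, tolerance = 1e-3)
})

test_that("without sequestration the sensor integrates and never falls", {
  loop <- abstractLoop(AIFParameters(eta = 0, theta1 = 1, theta2 = 1), 2,
                       gammaP = 1, x1Init = 1)
  tr <- simulateClosedLoop(loop, c(0, 50), seq(0, 50, 0.5))
  expect_true(all(diff(trajValues(tr)[, "z2"]) >= -1e-9))
})

test_that("tracking MSE matches its definition and symmetries", {
  ref <- refFromValues(0:96, rep(2, 97))
  mk <- function(v) Trajectory(0:96, matrix(v, ncol = 1,
                                            dimnames = list(NULL, "x1")))
  expect_equal(mse(trackingMSE(ref, mk(rep(2, 97)), "x1")), 0)
  expect_equal(mse(trackingMSE(ref, mk(rep(2.5, 97)), "x1")), 0.25)
  m <- trackingMSE(ref, mk(rep(2.5, 97)), "x1")
  expect_equal(m@nPoints, 96L)
  # symmetric in the two signals, invariant to adding the same function
  set.seed(8)
  f <- runif(97); g <- runif(97)
  ref1 <- refFromValues(0:96, f + 1); ref2 <- refFromValues(0:96, g + 1)
  expect_equal(mse(trackingMSE(ref1, mk(g + 1), "x1")),
               mse(trackingMSE(ref2, mk(f + 1), "x1")))
  h <- sin(0:96 / 5) + 2
  expect_equal(mse(trackingMSE(refFromValues(0:96, f + 1 + h), mk(g + 1 + h), "x1")),
               mse(trackingMSE(ref1, mk(g + 1), "x1")), tolerance = 1e-10)
  expect_error(trackingMSE(ref1, mk(f), "nope"), "no column")
})

test_that("integral action is exact without controller degradation", {
  cl <- loadClock("AD2015")
  ref <- clockReference(cl)
  pert <- applyLossOfFunction(cl$model, "FRQ", "WC1")
  eb <- etaBar(1, 1, cl$spec@gammaP, ref@muMin)
  mkrun <- function(gC) {
    loop <- closedLoop(pert, "FRQ", AIFParameters(10 * eb, 3, 1, gC), ref,
                       unperturbed = cl$model)
    simulateClosedLoop(loop, c(0, 24), seq(0, 24, 0.005))
  }
  tr0 <- mkrun(0)
  r0 <- integralResidual(tr0, ref, theta2 = 1, targetSpecies = "FRQ")
  expect_equal(r0[1], 0)
  z <- trajValues(tr0)[, "z1"] - trajValues(tr0)[, "z2"]
  expect_lt(max(abs(r0)), 1e-4 * (1 + max(abs(z))))
  # controller degradation breaks the identity, and the diagnostic sees it
  tr5 <- mkrun(0.5)
  r5 <- integralResidual(tr5, ref, theta2 = 1, targetSpecies = "FRQ")
  expect_gt(max(abs(r5)), 100 * max(abs(r0)))
})
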