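## A cheap closed loop for sweep mechanics: abstract plant, constant
## set point.
cheapLoop <- function(gammaC = 0) {
  abstractLoop(AIFParameters(eta = 200, theta1 = 1, theta2 = 1,
                             gammaC = gammaC),
               constantReference(2, horizon = 200), gammaP = 1)
}

test_that("a single-point sweep returns that point as the optimum", {
  sw <- sweepParameter(cheapLoop(), "theta1", 2.5, mseGrid = 1:96)
  expect_equal(sw@optimum$value, 2.5)
  expect_equal(sw@optimum$mse, sw@mse[1])
  expect_equal(length(sw@grid), 1L)
})

test_that("sweeps are deterministic and record the fixed parameters", {
  g <- c(0.5, 1, 2, 4)
  sw1 <- sweepParameter(cheapLoop(), "theta1", g)
  sw2 <- sweepParameter(cheapLoop(), "theta1", g)
  expect_identical(sw1@mse, sw2@mse)
  expect_identical(sw1@optimum, sw2@optimum)
  expect_equal(sw1@fixedParams@eta, 200)
  expect_error(sweepParameter(cheapLoop(), "theta1", c(2, 1)), "increasing")
})

test_that("more sequestration never hurts between 0.1 and 10 times the bound", {
  for (id in c("JL2005", "AD2015")) {
    cl <- loadClock(id); ref <- clockReference(cl)
    eb <- etaBar(1, 1, cl$spec@gammaP, ref@muMin)
    loop <- clockAIF:::.clockLoop(cl, ref, AIFParameters(eb, 1, 1, 0))
    sw <- sweepParameter(loop, "eta", eb * 10^seq(-1, 1, length.out = 7))
    expect_true(all(diff(sw@mse) <= 1e-6))
    expect_lte(sw@mse[7], sw@mse[1])
  }
})

test_that("controller degradation degrades tracking on the packaged clocks", {
  # beyond the smallest nonzero degradation the MSE rises monotonically
  # (a small damping dip can occur at gammaC = 0.5 when the actuation is
  # aggressive), and any degradation at or past the transition is worse
  # than none
  for (id in c("JL2005", "SB2004")) {
    cl <- loadClock(id); ref <- clockReference(cl)
    eb <- etaBar(1, 1, cl$spec@gammaP, ref@muMin)
    loop <- clockAIF:::.clockLoop(cl, ref, AIFParameters(10 * eb, 1, 1, 0))
    sw0 <- sweepParameter(loop, "theta1", clockAIF:::.theta1GridZero())
    loop@params@theta1 <- sw0@optimum$value
    swg <- sweepParameter(loop, "gammaC", c(0, 0.5, 1, 1.5, 2, 3, 5))
    m <- swg@mse
    expect_true(all(diff(m[-1]) >= -0.05 * m[-(1:2)]))
    expect_gt(m[4], m[1])          # gammaC = 1.5 worse than 0
    expect_equal(which.max(m), 7L) # strongest degradation is worst
  }
})

test_that("the transition heuristic needs a falling MSE curve", {
  # with no actuation the loop is inert: MSE is flat in eta -> error
  spec <- ClockModelSpec("JD2016", "HYP", "PIF", 0)
  ref <- clockReference("JD2016")
  cl <- loadClock("JD2016")
  pert <- applyLossOfFunction(cl$model, "HYP", "PIF")
  loop <- closedLoop(pert, "HYP", AIFParameters(1, 0, 0, 0), ref,
                     plantInit = cl$model@initial)
  expect_error(chooseEta(spec, ref, cls = loop,
                         etaGrid = c(1, 10, 100)), "no MSE transition")
  expect_error(chooseEta(spec, ref, cls = NULL), "required")
})

test_that("chooseEta applies the tenfold rule when the bound exists", {
  cl <- loadClock("AD2015"); ref <- clockReference(cl)
  expect_equal(chooseEta(cl$spec, ref),
               10 * etaBar(1, 1, cl$spec@gammaP, ref@muMin))
  expect_equal(chooseEta(cl$spec, ref, theta1 = 2, theta2 = 3),
               10 * etaBar(2, 3, cl$spec@gammaP, ref@muMin))
})

test_that("the designed controller beats the uncontrolled perturbed clock", {
  rep1 <- designController("JL2005", gammaCPolicy = "zero")
  expect_equal(rep1@chosen@gammaC, 0)
  expect_equal(rep1@chosen@theta2, 1)
  expect_equal(rep1@chosen@eta, 10 * rep1@etaBar)
  expect_lt(rep1@finalMSE, uncontrolledMSE("JL2005"))
  expect_named(rep1@stepLog, paste0("step", 1:5))
  # determinism of the full procedure
  rep2 <- designController("JL2005", gammaCPolicy = "zero")
  expect_equal(rep1@finalMSE, rep2@finalMSE)
  expect_equal(rep1@chosen, rep2@chosen)
  # fixed-gammaC policy is passed through
  rep3 <- designController("JL2005", gammaCPolicy = "fixed", gammaC = 1.5)
  expect_equal(rep3@chosen@gammaC, 1.5)
  expect_lt(rep3@finalMSE, uncontrolledMSE("JL2005"))
})
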