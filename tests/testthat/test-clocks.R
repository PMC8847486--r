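clockIds <- c("JL2005", "JD2016", "HU2001", "SB2004", "AD2015")

test_that("the five packaged clocks load with their design triples", {
  expected <- list(
    JL2005 = c("LHY_CCA1", "TOC1"), JD2016 = c("HYP", "PIF"),
    HU2001 = c("PER", "CLK_CYC"), SB2004 = c("BMAL1", "PER2_CRY"),
    AD2015 = c("FRQ", "WC1"))
  gammaPs <- c(JL2005 = 1.2875, JD2016 = 0, HU2001 = 0.5238,
               SB2004 = 1.5816, AD2015 = 0.2749)
  for (id in clockIds) {
    cl <- loadClock(id)
    expect_s4_class(cl$model, "SSystemModel")
    expect_gte(length(speciesNames(cl$model)), 3)
    expect_identical(cl$spec@targetSpecies, expected[[id]][1])
    expect_identical(cl$spec@lostRegulator, expected[[id]][2])
    expect_equal(cl$spec@gammaP, unname(gammaPs[id]))
    expect_true(cl$spec@targetSpecies %in% speciesNames(cl$model))
  }
  expect_error(loadClock("XX9999"), "unknown clock id")
})

test_that("loading the same clock twice yields identical models", {
  a <- loadClock("SB2004"); b <- loadClock("SB2004")
  expect_equal(a$model, b$model)
  expect_equal(a$spec, b$spec)
})

test_that("reference profiles are entrained, positive, and 24 h periodic", {
  for (id in setdiff(clockIds, "JD2016")) {
    ref <- clockReference(id)
    expect_gt(ref@muMin, 0)
    expect_true(ref@metadata$entrained)
    # day-over-day agreement within 1% of amplitude over the 96 h window
    f <- function(t) evaluateReference(ref, t)
    tt <- seq(0, 72, by = 0.5)
    expect_lt(max(abs(f(tt) - f(tt + 24))) / (ref@muMax - ref@muMin), 0.01)
  }
})

test_that("reference extremes match the design metadata they were built to", {
  for (id in c("HU2001", "SB2004")) {
    cl <- loadClock(id)
    ref <- clockReference(cl)
    expect_equal(muRange(ref), cl$spec@publishedMuRange, tolerance = 0.01)
  }
})

test_that("the hypocotyl-growth reference is non-decreasing and non-periodic", {
  ref <- clockReference("JD2016")
  expect_false(ref@periodic)
  expect_true(all(diff(ref@values) >= -1e-9))
  expect_equal(ref@muMin, ref@values[1])
  expect_error(evaluateReference(ref, 120), "wrapping is disabled")
})

test_that("reference evaluation interpolates linearly and reproduces samples", {
  ref <- refFromValues(c(0, 1, 2, 3), c(1, 1, 3, 2))
  expect_equal(evaluateReference(ref, c(0, 1, 2, 3)), c(1, 1, 3, 2))
  expect_equal(evaluateReference(ref, 0.5), 1)    # midpoint of equal neighbors
  expect_equal(evaluateReference(ref, 1.5), 2)    # linear between 1 and 3
  # periodic wrap: window is [0, 3]; t = 24.5 wraps by 24 to 0.5
  out <- evaluateReference(ref, 24.5)
  expect_equal(as.numeric(out), 1)
  expect_true(isTRUE(attr(out, "wrapped")))
})

test_that("a constant species yields a degenerate reference", {
  m <- SSystemModel("X", production = list(X = list(alpha = 1)),
                    degradation = list(X = list(list(beta = 1, exponents = noexp))),
                    initial = c(X = 1))
  ref <- referenceProfile(m, "X", windowHours = 48, transientDays = 1)
  expect_equal(ref@muMin, ref@muMax, tolerance = 1e-8)
})
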