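## A minimal problem whose predictions are known in closed form: a model
## with zero production and zero degradation stays at its initial state,
## so the simulated series is flat at the first training sample.
flatProblem <- function(data, times = seq_along(data) - 1) {
  m <- SSystemModel("X",
                    degradation = list(X = list(list(beta = 0, exponents = noexp))),
                    initial = c(X = data[1]))
  tr <- Trajectory(times, matrix(data, ncol = 1, dimnames = list(NULL, "X")))
  estimationProblem(m, tr, data.frame(address = "X|beta|1", kind = "rate"))
}

test_that("objective implements the normalized least-squares formula", {
  # data (1, 2), predictions (1, 1), M = 2: (1/2) ((0/2)^2 + (1/2)^2) = 0.125
  pr <- flatProblem(c(1, 2))
  expect_equal(ssObjective(pr, 0), 0.125)
  # scaling a species' data (and hence its flat prediction) leaves its
  # contribution unchanged: M scales with the data
  for (c_ in c(0.1, 3, 50))
    expect_equal(ssObjective(flatProblem(c_ * c(1, 2)), 0), 0.125)
})

test_that("objective is zero iff predictions reproduce the data", {
  toy <- makeToyProblem(1)
  expect_lt(ssObjective(toy$problem, toy$theta), 1e-10)
  off <- toy$theta * 1.3
  expect_gt(ssObjective(toy$problem, off), 1e-6)
})

test_that("objective is invariant to species reordering", {
  toy <- makeToyProblem(2)
  pr <- toy$problem
  m <- pr@template
  sp <- rev(m@species)
  m2 <- SSystemModel(sp, production = m@production[sp],
                     degradation = m@degradation[sp], light = m@light[sp],
                     initial = m@initial[sp])
  tr <- pr@training
  tr2 <- Trajectory(tr@times, tr@values[, sp], tr@schedule)
  pr2 <- estimationProblem(m2, tr2, pr@free, pr@schedule)
  expect_equal(ssObjective(pr2, toy$theta * 1.15),
               ssObjective(pr, toy$theta * 1.15), tolerance = 1e-9)
})

test_that("failed simulations return the finite penalty, not an error", {
  toy <- makeToyProblem(1)
  # an absurd production rate blows the state up to Inf mid-run
  bad <- toy$theta
  bad[["X2|alpha"]] <- 1e200
  v <- ssObjective(toy$problem, bad)
  expect_true(is.finite(v))
  expect_equal(as.numeric(v), 1e6)
  expect_true(isTRUE(attr(v, "penalty")))
})

test_that("toy fixtures follow the four-day 12L:12D training protocol", {
  toy1 <- makeToyProblem(5)
  toy2 <- makeToyProblem(5)
  expect_equal(toy1$problem@training@values, toy2$problem@training@values)
  expect_equal(toy1$theta, toy2$theta)
  tr <- toy1$problem@training
  expect_equal(length(trajTimes(tr)), 49)  # two days, hourly: N_L = 49
  expect_equal(range(trajTimes(tr)), c(0, 48))
  expect_equal(unname(toy1$problem@normalizers),
               unname(apply(tr@values, 2, max)))
})

test_that("fitting is deterministic and starts from the supplied point", {
  toy <- makeToyProblem(4)
  f1 <- fitSSystem(toy$problem, toy$theta * 1.1, maxIter = 40, restarts = 1, seed = 9)
  f2 <- fitSSystem(toy$problem, toy$theta * 1.1, maxIter = 40, restarts = 1, seed = 9)
  expect_identical(f1@thetaHat, f2@thetaHat)
  expect_identical(f1@objectiveValue, f2@objectiveValue)
  # starting at the truth: the best value can never exceed the start value
  f0 <- fitSSystem(toy$problem, toy$theta, maxIter = 5, restarts = 0, seed = 1)
  expect_lt(f0@objectiveValue, 1e-10)
  # sign constraints are enforced
  bad <- toy$theta; bad[5] <- 0
  expect_error(fitSSystem(toy$problem, bad, seed = 1), "nonzero")
  # objective value is consistent with re-evaluation at the optimum
  expect_equal(as.numeric(ssObjective(toy$problem, f1@thetaHat)),
               f1@objectiveValue, tolerance = 1e-12)
})

test_that("parameters are recovered from 20%-perturbed starts across seeds", {
  allrel <- numeric(0)
  for (s in 1:10) {
    toy <- makeToyProblem(s)
    fit <- fitSSystem(toy$problem, init = toy$theta * 1.2,
                      maxIter = 2500, restarts = 0, seed = s)
    expect_lt(fit@objectiveValue, 1e-4)
    allrel <- c(allrel, abs(fit@thetaHat - toy$theta) / abs(toy$theta))
    # exponent signs were preserved
    expect_equal(sign(fit@thetaHat[c("X1|g|1", "X2|g|1")]),
                 sign(toy$theta[c("X1|g|1", "X2|g|1")]))
  }
  expect_lt(median(allrel), 0.10)
})
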