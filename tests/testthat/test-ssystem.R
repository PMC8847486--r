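test_that("derivative assembles production, degradation and light terms", {
  # constant production vs linear decay: 2 - 1*1 = 1
  m <- SSystemModel("X", production = list(X = list(alpha = 2)),
                    degradation = list(X = list(list(beta = 1, exponents = noexp))))
  expect_equal(unname(ssDerivative(m, 1, 0)), 1)

  # inhibitory production factor: 1 * 2^-1 = 0.5
  m2 <- SSystemModel(c("A", "B"),
    production = list(A = list(alpha = 1,
                               factors = list(list(members = "B", exponent = -1)))))
  expect_equal(unname(ssDerivative(m2, c(1, 2), 0)), c(0.5, 0))

  # light-gated additive term contributes only when its gate is open
  m3 <- SSystemModel("X",
    light = list(X = list(list(gamma = 0.5, gate = "light", factor = NULL),
                          list(gamma = 0.2, gate = "dark", factor = NULL))))
  expect_equal(unname(ssDerivative(m3, 1, t = 5, LightSchedule(12))), 0.5)
  expect_equal(unname(ssDerivative(m3, 1, t = 13, LightSchedule(12))), 0.2)
})

test_that("one-factor-per-species models reduce to the classic power-law form", {
  set.seed(42)
  for (rep_ in 1:5) {
    n <- sample(2:4, 1)
    a <- runif(n, 0.5, 2); b <- runif(n, 0.2, 1)
    G <- matrix(runif(n * n, -1.5, 1.5) * rbinom(n * n, 1, 0.5), n)
    H <- matrix(runif(n * n, 0, 1) * rbinom(n * n, 1, 0.4), n)
    sp <- paste0("S", seq_len(n))
    production <- degradation <- list()
    for (i in seq_len(n)) {
      production[[sp[i]]] <- list(alpha = a[i], factors = lapply(
        which(G[i, ] != 0),
        function(j) list(members = sp[j], exponent = G[i, j])))
      # classic degradation b_i prod X^H: represent as beta * X_i * prod X^h
      # with h = H - e_i on the diagonal
      h <- H[i, ]; h[i] <- h[i] - 1
      degradation[[sp[i]]] <- list(list(beta = b[i], exponents = setNames(h, sp)))
    }
    m <- SSystemModel(sp, production, degradation)
    x <- runif(n, 0.3, 3)
    expect_equal(unname(ssDerivative(m, x, 0)), classicDeriv(x, a, b, G, H),
                 tolerance = 1e-12)
  }
})

test_that("non-finite derivatives are reported with the species name", {
  m <- SSystemModel(c("A", "B"),
    production = list(A = list(alpha = 1,
                               factors = list(list(members = "B", exponent = -500)))))
  # B = 0 is clipped to 1e-9; (1e-9)^-500 overflows to Inf
  expect_error(ssDerivative(m, c(1, 0), 0), "A")
})

test_that("loss-of-function zeroes the positive input and nothing else", {
  cl <- loadClock("AD2015")
  pert <- applyLossOfFunction(cl$model, "FRQ", "WC1")
  set.seed(7)
  for (i in 1:20) {
    x <- runif(3, 0.05, 4)
    d0 <- ssDerivative(cl$model, x, t = 5)
    d1 <- ssDerivative(pert, x, t = 5)
    # production contribution gone: perturbed rate never exceeds native
    expect_lte(d1[["FRQ"]], d0[["FRQ"]] + 1e-12)
    # other species untouched
    expect_equal(d1[c("WC1", "WCC")], d0[c("WC1", "WCC")])
  }
  # the removed production is zero at every state: FRQ rate no longer
  # depends on the lost regulator
  x <- c(FRQ = 1, WC1 = 0.5, WCC = 1)
  x2 <- x; x2[["WC1"]] <- 3
  expect_equal(ssDerivative(pert, x, 5)[["FRQ"]],
               ssDerivative(pert, x2, 5)[["FRQ"]])
})

test_that("negative regulation through degradation survives the perturbation", {
  cl <- loadClock("HU2001")
  pert <- applyLossOfFunction(cl$model, "PER", "CLK_CYC")
  x <- c(PER = 1, CLK_CYC = 1, PER_TIM = 0.5)
  x2 <- x; x2[["PER_TIM"]] <- 2
  d1 <- ssDerivative(pert, x, 5)[["PER"]]
  d2 <- ssDerivative(pert, x2, 5)[["PER"]]
  expect_lt(d2, d1)  # more complex, faster PER clearance
})

test_that("a no-op selector returns an identical model; bad selectors are named", {
  cl <- loadClock("AD2015")
  same <- applyLossOfFunction(cl$model, "FRQ", NULL)
  x <- c(0.5, 1, 2)
  expect_equal(ssDerivative(same, x, 3), ssDerivative(cl$model, x, 3))
  expect_error(applyLossOfFunction(cl$model, "FRQ", "NOSUCH"), "WC1")
  expect_error(applyLossOfFunction(cl$model, "NOSUCH"), "unknown target")
})
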