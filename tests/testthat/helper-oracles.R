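## Independent reference implementations used as oracles. These are
## deliberately written from the mathematical definitions, without using
## any of the package's simulation code paths.

noexp <- setNames(numeric(0), character(0))

## Fixed-step classical RK4 integrator; f(t, y) -> dy. Piecewise light
## handling is the caller's job (step size must divide the segment).
rk4Integrate <- function(f, y0, t0, t1, h) {
  n <- round((t1 - t0) / h)
  stopifnot(abs(n * h - (t1 - t0)) < 1e-9)
  y <- y0
  out <- matrix(NA_real_, n + 1, length(y0))
  out[1, ] <- y
  t <- t0
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * h
    out[i + 1, ] <- y
  }
  out
}

## Classic power-law form: dXi/dt = a_i prod_j X_j^{G[i,j]} - b_i prod_j X_j^{H[i,j]}
classicDeriv <- function(x, a, b, G, H) {
  x <- pmax(x, 1e-9)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    a[i] * prod(x^G[i, ]) - b[i] * prod(x^H[i, ])
  }, numeric(1))
}

## Square-wave light, written independently of the package helper.
lightAt <- function(t, ph) as.numeric((t - floor(t / 24) * 24) < ph)

## The standard two-gene test oscillator: light-driven repressilator pair.
## X1 is produced under repression by X2 and driven by light; X2 is
## activated by X1. Used both as a simulator fixture and (hand-coded
## below) as the RK4 oracle's right-hand side.
toyPars <- list(a1 = 1.2, a2 = 0.8, b1 = 0.6, b2 = 0.4,
                g12 = -1.1, g21 = 0.9, gl = 0.8)

toyOscillator <- function(p = toyPars) {
  SSystemModel(
    c("X1", "X2"),
    production = list(
      X1 = list(alpha = p$a1, factors = list(list(members = "X2", exponent = p$g12))),
      X2 = list(alpha = p$a2, factors = list(list(members = "X1", exponent = p$g21)))),
    degradation = list(
      X1 = list(list(beta = p$b1, exponents = noexp)),
      X2 = list(list(beta = p$b2, exponents = noexp))),
    light = list(X1 = list(list(gamma = p$gl, gate = "light", factor = NULL))),
    initial = c(X1 = 1, X2 = 1))
}

toyDerivOracle <- function(t, y, p = toyPars, ph = 12) {
  y <- pmax(y, 1e-9)
  c(p$a1 * y[2]^p$g12 - p$b1 * y[1] + p$gl * lightAt(t, ph),
    p$a2 * y[1]^p$g21 - p$b2 * y[2])
}

## One-species exponential-decay model (alpha = 0, linear degradation).
decayModel <- function(beta = 1) {
  SSystemModel("X",
               degradation = list(X = list(list(beta = beta, exponents = noexp))),
               initial = c(X = 1))
}

## Simple hand-made reference signal over [0, 48]: hourly triangle-ish.
refFromValues <- function(times, values, periodic = TRUE) {
  ReferenceSignal(times, values, periodic = periodic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
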