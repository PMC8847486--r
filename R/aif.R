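#' Sequestration-rate design bound
#'
#' For the one-process-species loop, time-scale separation between plant
#' and controller requires the sequestration rate eta to be much larger
#' than \deqn{\bar\eta = (\theta_1 \theta_2 / \gamma_P)^2 (1/\mu),}
#' evaluated at the reference floor \code{mu = mu_min}. When the target
#' species has no degradation (\code{gammaP = 0}) the bound involves a
#' division by zero and is undefined; \code{NA} is returned and the
#' transition-point heuristic of \code{\link{chooseEta}} applies instead.
#'
#' @param theta1 actuation rate (1/h).
#' @param theta2 sensing rate (1/h).
#' @param gammaP target species degradation rate (1/h).
#' @param muMin reference floor, must be > 0.
#' @return The bound (1/(nM h)), or \code{NA_real_} when \code{gammaP = 0}.
#' @examples
#' etaBar(1, 1, 1.2875, 1.3920)
#' etaBar(1, 1, 0, 6.2713)  # undefined: NA
#' @export
etaBar <- function(theta1, theta2, gammaP, muMin) {
  stopifnot(is.finite(theta1), is.finite(theta2), is.finite(gammaP),
            theta1 >= 0, theta2 >= 0, gammaP >= 0)
  if (!is.finite(muMin) || muMin <= 0)
    stop("muMin must be a positive number")
  if (gammaP == 0) return(NA_real_)
  (theta1 * theta2 / gammaP)^2 / muMin
}

#' Build a closed-loop system
#'
#' Embeds the AIF controller into a perturbed clock model: the target
#' species' lost production is replaced by the actuation term
#' \code{theta1 * z1}, the sensor species integrates \code{theta2 * x1},
#' and both controller species sequester each other at rate eta. Unless an
#' explicit plant initial state is given, the plant starts on the
#' unperturbed entrained cycle at dawn (controller and perturbation engage
#' simultaneously at t = 0); the controller starts empty
#' (z1(0) = z2(0) = 0).
#'
#' @param plant the perturbed \code{SSystemModel} (see
#'   \code{\link{applyLossOfFunction}}).
#' @param targetSpecies the controlled output species x1.
#' @param params \code{AIFParameters}.
#' @param reference \code{ReferenceSignal} mu(t).
#' @param schedule light schedule driving the plant.
#' @param plantInit optional named plant initial state; defaults to the
#'   entrained state at dawn of the unperturbed model when
#'   \code{unperturbed} is supplied, else to the plant's stored initial
#'   state.
#' @param unperturbed optional unperturbed \code{SSystemModel} used to
#'   compute the entrained initial state.
#' @param controllerInit numeric length 2, (z1(0), z2(0)).
#' @return A \code{ClosedLoopSystem}.
#' @export
closedLoop <- function(plant, targetSpecies, params, reference,
                       schedule = LightSchedule(12), plantInit = NULL,
                       unperturbed = NULL, controllerInit = c(0, 0)) {
  stopifnot(is(plant, "SSystemModel"), is(params, "AIFParameters"))
  if (is.null(plantInit)) {
    plantInit <- if (!is.null(unperturbed)) {
      tr <- entrainedCycle(unperturbed, schedule, transientDays = 2,
                           recordDays = 1, dt = 1)
      setNames(tr@values[1, ], colnames(tr@values))
    } else plant@initial
  }
  new("ClosedLoopSystem", plant = plant, targetSpecies = targetSpecies,
      params = params, reference = reference,
      plantInit = plantInit[plant@species],
      controllerInit = as.numeric(controllerInit),
      gammaP = NA_real_, schedule = schedule)
}

#' @param gammaP plant degradation rate for the abstract one-species mode.
#' @param x1Init initial plant state for the abstract mode.
#' @rdname closedLoop
#' @export
abstractLoop <- function(params, reference, gammaP, x1Init = 0,
                         controllerInit = c(0, 0)) {
  stopifnot(is(params, "AIFParameters"))
  if (is.numeric(reference)) reference <- constantReference(reference)
  new("ClosedLoopSystem", plant = NULL, targetSpecies = "x1",
      params = params, reference = reference,
      plantInit = c(x1 = as.numeric(x1Init)),
      controllerInit = as.numeric(controllerInit),
      gammaP = as.numeric(gammaP), schedule = NULL)
}

## Compiled RHS factory for the augmented system. Returns function(t, y, L).
.closedLoopRHS <- function(cls) {
  p <- cls@params
  muf <- .referenceFun(cls@reference)
  eta <- p@eta; th1 <- p@theta1; th2 <- p@theta2; gC <- p@gammaC
  if (is.null(cls@plant)) {
    gP <- cls@gammaP
    function(t, y, L) {
      y <- pmax(y, 0)
      x1 <- y[1]; z1 <- y[2]; z2 <- y[3]
      mu <- muf(t)
      seq_ <- eta * z1 * z2
      c(th1 * z1 - gP * x1,
        mu - seq_ - gC * z1,
        th2 * x1 - seq_ - gC * z2)
    }
  } else {
    C <- .compileModel(cls@plant)
    ti <- match(cls@targetSpecies, cls@plant@species)
    n <- C$n
    function(t, y, L) {
      y <- pmax(y, 0)
      x <- y[seq_len(n)]; z1 <- y[n + 1]; z2 <- y[n + 2]
      mu <- muf(t)
      dx <- .ssDeriv(x, L, C)
      dx[ti] <- dx[ti] + th1 * z1
      seq_ <- eta * z1 * z2
      c(dx,
        mu - seq_ - gC * z1,
        th2 * x[ti] - seq_ - gC * z2)
    }
  }
}

#' Closed-loop right-hand side
#'
#' Derivative of the augmented state (plant species..., z1, z2). Plant
#' species follow their native power-law dynamics, except that the target
#' species receives the actuation \code{theta1 * z1} in place of its lost
#' production. The controller obeys
#' \code{dz1/dt = mu(t) - eta z1 z2 - gammaC z1} and
#' \code{dz2/dt = theta2 x1 - eta z1 z2 - gammaC z2}; the sequestration
#' flux \code{eta z1 z2} is shared exactly between the two rates.
#'
#' @param cls a \code{ClosedLoopSystem}.
#' @param state augmented state vector, length n_plant + 2.
#' @param t time (h).
#' @return Named derivative vector.
#' @export
closedLoopDerivative <- function(cls, state, t = 0) {
  stopifnot(is(cls, "ClosedLoopSystem"))
  n <- length(cls@plantInit)
  if (length(state) != n + 2L)
    stop(sprintf("augmented state must have length %d (plant) + 2 (controller)", n))
  rhs <- .closedLoopRHS(cls)
  L <- if (is.null(cls@schedule)) 0L else lightSignal(cls@schedule, t)
  setNames(rhs(t, as.numeric(state), L),
           c(names(cls@plantInit), "z1", "z2"))
}

#' Simulate the closed loop
#'
#' Integrates the augmented plant + controller system with the same
#' piecewise, event-exact solver policy as \code{\link{simulateModel}}.
#' Controller species get a tighter absolute tolerance (1e-12) since at
#' large sequestration rates they equilibrate at very small copy numbers.
#'
#' @param cls a \code{ClosedLoopSystem}.
#' @param tSpan integration window (default \code{c(0, 96)} h).
#' @param outputGrid recording times (default every 0.1 h).
#' @param rtol,atol solver tolerances (plant species).
#' @return An augmented \code{Trajectory} with columns for the plant
#'   species, \code{z1}, \code{z2} and the reference \code{mu}.
#' @export
simulateClosedLoop <- function(cls, tSpan = c(0, 96),
                               outputGrid = seq(tSpan[1], tSpan[2], by = 0.1),
                               rtol = 1e-6, atol = 1e-9) {
  stopifnot(is(cls, "ClosedLoopSystem"))
  rhs <- .closedLoopRHS(cls)
  y0 <- c(as.numeric(cls@plantInit), cls@controllerInit)
  atolv <- c(rep(atol, length(cls@plantInit)), 1e-12, 1e-12)
  res <- .integratePiecewise(rhs, y0, tSpan, outputGrid, cls@schedule,
                             rtol = rtol, atol = atolv)
  mu <- vapply(res$times, .referenceFun(cls@reference), numeric(1))
  vals <- cbind(res$values, mu)
  colnames(vals) <- c(names(cls@plantInit), "z1", "z2", "mu")
  Trajectory(res$times, vals, cls@schedule,
             metadata = list(nclip = res$nclip, params = cls@params,
                             target = cls@targetSpecies,
                             solver = list(method = "lsoda", rtol = rtol,
                                           atol = atol)))
}

#' Reference-tracking mean square error
#'
#' \deqn{MSE = (1/N_T) \sum_t (\mu(t) - x_1(t))^2} over an hourly grid
#' (t = 1..96 by default, N_T = 96). The controlled output is read from
#' the trajectory by linear interpolation.
#'
#' @param reference a \code{ReferenceSignal}.
#' @param traj a \code{Trajectory} containing the target series.
#' @param targetSpecies column of \code{traj} to compare against the
#'   reference.
#' @param grid evaluation times; must lie within both signals' support.
#' @return A \code{TrackingMetric}.
#' @export
trackingMSE <- function(reference, traj, targetSpecies, grid = 1:96) {
  stopifnot(is(reference, "ReferenceSignal"), is(traj, "Trajectory"))
  if (!targetSpecies %in% colnames(traj@values))
    stop(sprintf("trajectory has no column '%s'", targetSpecies))
  if (min(grid) < min(traj@times) - 1e-9 || max(grid) > max(traj@times) + 1e-9)
    stop("evaluation grid must lie within the trajectory support")
  x1 <- stats::approx(traj@times, traj@values[, targetSpecies], xout = grid)$y
  mu <- evaluateReference(reference, grid)
  new("TrackingMetric", mse = mean((mu - x1)^2),
      nPoints = length(grid), grid = as.numeric(grid))
}

#' @rdname trackingMSE
#' @param x a \code{TrackingMetric}.
#' @export
mse <- function(x) { stopifnot(is(x, "TrackingMetric")); x@mse }

#' Integral-action diagnostic
#'
#' With zero controller degradation, the difference of the controller
#' species is an exact running integral of the tracking error:
#' \deqn{z_1(t) - z_2(t) - (z_1(0) - z_2(0)) = \int_0^t (\mu - \theta_2 x_1) d\tau.}
#' This function returns the residual of that identity over time
#' (trapezoidal quadrature on the trajectory grid). For a run with
#' \code{gammaC = 0} the residual is numerically zero; a materially
#' nonzero residual diagnoses broken integral action (e.g. a run with
#' controller degradation).
#'
#' @param traj an augmented closed-loop \code{Trajectory} (columns z1, z2
#'   present).
#' @param reference the \code{ReferenceSignal} used in the run.
#' @param theta2 sensing rate used in the run.
#' @param targetSpecies the output species column.
#' @return Numeric residual vector over \code{trajTimes(traj)}; its first
#'   element is exactly 0.
#' @export
integralResidual <- function(traj, reference, theta2, targetSpecies) {
  stopifnot(is(traj, "Trajectory"),
            all(c("z1", "z2") %in% colnames(traj@values)))
  tt <- traj@times
  z <- traj@values[, "z1"] - traj@values[, "z2"]
  x1 <- traj@values[, targetSpecies]
  mu <- if ("mu" %in% colnames(traj@values)) traj@values[, "mu"] else
    evaluateReference(reference, tt)
  f <- mu - theta2 * x1
  cumint <- c(0, cumsum(diff(tt) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  (z - z[1]) - cumint
}
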