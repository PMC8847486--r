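setClassUnion("ListOrNULL", c("list", "NULL"))

#' Square-wave light schedule
#'
#' A periodic light-dark forcing signal with a 24 h cycle and dawn at
#' \code{t = 0}. The signal is exactly 1 during the light interval
#' \code{[0, photoperiod)} of each cycle and exactly 0 otherwise.
#' \code{photoperiod = 0} is constant dark (DD), \code{photoperiod = 24}
#' constant light (LL), and \code{photoperiod = 12} the symmetric 12L:12D
#' cycle.
#'
#' @slot photoperiod hours of light per 24 h cycle, in [0, 24].
#' @export
setClass("LightSchedule", representation(photoperiod = "numeric"))

setValidity("LightSchedule", function(object) {
  p <- object@photoperiod
  if (length(p) != 1L || !is.finite(p)) return("photoperiod must be a single finite number")
  if (p < 0 || p > 24) return("photoperiod must lie in [0, 24] hours")
  TRUE
})

#' @param photoperiod hours of light per 24 h cycle (P_H), in [0, 24].
#' @return A \code{LightSchedule} object.
#' @rdname LightSchedule-class
#' @examples
#' ld <- LightSchedule(12)  # 12L:12D
#' lightSignal(ld, c(5, 13, 37))
#' @export
LightSchedule <- function(photoperiod = 12) {
  new("LightSchedule", photoperiod = as.numeric(photoperiod))
}

#' Extended S-System model of a gene circuit
#'
#' Power-law ODE model in which each species has one production block (a
#' rate constant times a product of power-law factors, each factor raised
#' to a real exponent whose sign encodes activation/inhibition), a list of
#' degradation terms (each proportional to the species itself, optionally
#' modulated by power-law cofactors), and a list of additive light-coupled
#' terms gated by a square-wave light signal.
#'
#' Internal term representation (all species referenced by name):
#' \itemize{
#'  \item \code{production[[i]]}: \code{list(alpha =, factors = list(
#'    list(members = <character>, exponent = <numeric>), ...))}. The factor
#'    base is the sum of the member species' concentrations.
#'  \item \code{degradation[[i]]}: list of \code{list(beta =, exponents =
#'    <named numeric>)}; the term is \code{beta * X_i * prod(X_k^h_k)}.
#'  \item \code{light[[i]]}: list of \code{list(gamma =, gate = "light"|"dark",
#'    factor = NULL | list(members =, exponent =))}; the term is
#'    \code{gamma * gate(L) * (sum X_members)^exponent} and vanishes
#'    whenever its gate is closed.
#' }
#'
#' @slot species ordered character vector of species identifiers.
#' @slot production per-species production blocks (see Details).
#' @slot degradation per-species degradation term lists.
#' @slot light per-species light-coupled term lists.
#' @slot initial named numeric vector, the stored initial state (nM).
#' @slot units named character vector of unit labels (metadata only).
#' @slot metadata free-form list (model id, provenance, design info).
#' @export
setClass("SSystemModel", representation(
  species     = "character",
  production  = "list",
  degradation = "list",
  light       = "list",
  initial     = "numeric",
  units       = "character",
  metadata    = "list"
))

.checkFactor <- function(f, species, where) {
  if (!is.list(f) || is.null(f$members) || is.null(f$exponent))
    return(sprintf("%s: factor must have 'members' and 'exponent'", where))
  if (length(f$members) < 1L)
    return(sprintf("%s: factor membership must select at least one species", where))
  bad <- setdiff(f$members, species)
  if (length(bad))
    return(sprintf("%s: unknown species in factor membership: %s", where,
                   paste(bad, collapse = ", ")))
  if (length(f$exponent) != 1L || !is.finite(f$exponent))
    return(sprintf("%s: factor exponent must be a single finite number", where))
  NULL
}

setValidity("SSystemModel", function(object) {
  msgs <- character(0)
  sp <- object@species
  n <- length(sp)
  if (n < 1L) msgs <- c(msgs, "model must have at least one species")
  if (anyDuplicated(sp)) msgs <- c(msgs, "species names must be unique")
  for (nm in c("production", "degradation", "light")) {
    sl <- slot(object, nm)
    if (length(sl) != n || !identical(names(sl), sp))
      msgs <- c(msgs, sprintf("slot '%s' must be a list named by and ordered as species", nm))
  }
  if (length(msgs)) return(msgs)
  for (i in seq_len(n)) {
    p <- object@production[[i]]
    if (!is.list(p) || is.null(p$alpha))
      msgs <- c(msgs, sprintf("production[%s]: missing alpha", sp[i]))
    else {
      if (!is.finite(p$alpha) || p$alpha < 0)
        msgs <- c(msgs, sprintf("production[%s]: alpha must be finite and >= 0", sp[i]))
      for (j in seq_along(p$factors)) {
        m <- .checkFactor(p$factors[[j]], sp, sprintf("production[%s] factor %d", sp[i], j))
        if (!is.null(m)) msgs <- c(msgs, m)
      }
    }
    for (j in seq_along(object@degradation[[i]])) {
      d <- object@degradation[[i]][[j]]
      if (!is.list(d) || is.null(d$beta) || !is.finite(d$beta) || d$beta < 0)
        msgs <- c(msgs, sprintf("degradation[%s] term %d: beta must be finite and >= 0", sp[i], j))
      else if (length(d$exponents)) {
        bad <- setdiff(names(d$exponents), sp)
        if (length(bad))
          msgs <- c(msgs, sprintf("degradation[%s] term %d: unknown cofactor species: %s",
                                  sp[i], j, paste(bad, collapse = ", ")))
        if (!all(is.finite(d$exponents)))
          msgs <- c(msgs, sprintf("degradation[%s] term %d: non-finite cofactor exponent", sp[i], j))
      }
    }
    for (j in seq_along(object@light[[i]])) {
      l <- object@light[[i]][[j]]
      if (!is.list(l) || is.null(l$gamma) || !is.finite(l$gamma))
        msgs <- c(msgs, sprintf("light[%s] term %d: gamma must be finite", sp[i], j))
      if (is.null(l$gate) || !l$gate %in% c("light", "dark"))
        msgs <- c(msgs, sprintf("light[%s] term %d: gate must be 'light' or 'dark'", sp[i], j))
      if (!is.null(l$factor)) {
        m <- .checkFactor(l$factor, sp, sprintf("light[%s] term %d", sp[i], j))
        if (!is.null(m)) msgs <- c(msgs, m)
      }
    }
  }
  if (length(object@initial) != n || !identical(names(object@initial), sp))
    msgs <- c(msgs, "initial state must be a numeric vector named by and ordered as species")
  else if (any(!is.finite(object@initial)) || any(object@initial < 0))
    msgs <- c(msgs, "initial state components must be finite and >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an extended S-System model
#'
#' @param species character vector of species identifiers.
#' @param production named list of production blocks, one per species:
#'   \code{list(alpha = <rate>, factors = list(list(members =, exponent =), ...))}.
#'   Species without an entry get \code{alpha = 0}.
#' @param degradation named list; each entry a list of
#'   \code{list(beta = <rate>, exponents = <named numeric>)} terms.
#' @param light named list; each entry a list of
#'   \code{list(gamma =, gate =, factor =)} terms.
#' @param initial named numeric initial state (defaults to 1 nM each).
#' @param units named character unit labels (metadata only, never converted).
#' @param metadata free-form list.
#' @return A validated \code{SSystemModel}.
#' @export
SSystemModel <- function(species, production = list(), degradation = list(),
                         light = list(), initial = NULL,
                         units = c(concentration = "nM", time = "h"),
                         metadata = list()) {
  species <- as.character(species)
  fill <- function(given, default) {
    out <- setNames(vector("list", length(species)), species)
    for (s in species) out[[s]] <- if (!is.null(given[[s]])) given[[s]] else default
    out
  }
  prod <- fill(production, list(alpha = 0, factors = list()))
  for (s in species) {
    if (is.null(prod[[s]]$factors)) prod[[s]]$factors <- list()
    prod[[s]]$alpha <- as.numeric(prod[[s]]$alpha)
  }
  if (is.null(initial)) initial <- setNames(rep(1, length(species)), species)
  initial <- initial[species]
  new("SSystemModel", species = species, production = prod,
      degradation = fill(degradation, list()), light = fill(light, list()),
      initial = initial, units = units, metadata = metadata)
}

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "SSystemModel", function(x) x@species)

#' Simulated trajectory container
#'
#' Time grid plus per-species concentration series produced by the ODE
#' simulator, together with the light schedule used and provenance
#' metadata (solver settings, number of negative-state clips, model id).
#'
#' @slot times strictly increasing numeric vector (h).
#' @slot values numeric matrix, one row per time, one column per series.
#' @slot schedule the \code{LightSchedule} used (may be \code{NULL} for
#'   unforced runs).
#' @slot metadata provenance list.
#' @export
setClass("Trajectory", representation(
  times = "numeric", values = "matrix", schedule = "ANY", metadata = "list"
))

setValidity("Trajectory", function(object) {
  msgs <- character(0)
  if (length(object@times) != nrow(object@values))
    msgs <- c(msgs, "times and values have inconsistent shapes")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (is.null(colnames(object@values)))
    msgs <- c(msgs, "values must have column names")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (any(object@values < 0))
    msgs <- c(msgs, "recorded concentrations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

Trajectory <- function(times, values, schedule = NULL, metadata = list()) {
  new("Trajectory", times = as.numeric(times), values = as.matrix(values),
      schedule = schedule, metadata = metadata)
}

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "Trajectory", function(x) colnames(x@values))

#' Reference circadian profile
#'
#' The target profile mu(t) that the feedback controller is asked to track:
#' a finely sampled time series of the unperturbed target gene, with its
#' extremes and a piecewise-linear interpolation rule. Oscillatory profiles
#' may be extended periodically (24 h wrap) beyond the stored window;
#' non-periodic profiles (monotone outputs such as hypocotyl growth) may
#' not.
#'
#' @slot times sample times (h), strictly increasing.
#' @slot values nonnegative profile samples (nM).
#' @slot muMin,muMax profile extremes over the stored window.
#' @slot periodic logical; whether 24 h periodic extension is allowed.
#' @slot metadata provenance list (model id, target species, window).
#' @export
setClass("ReferenceSignal", representation(
  times = "numeric", values = "numeric", muMin = "numeric", muMax = "numeric",
  periodic = "logical", metadata = "list"
))

setValidity("ReferenceSignal", function(object) {
  msgs <- character(0)
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (length(object@times) < 2L)
    msgs <- c(msgs, "a reference needs at least two samples")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@values < 0)) msgs <- c(msgs, "mu values must be >= 0")
  if (!isTRUE(all.equal(object@muMin, min(object@values))) ||
      !isTRUE(all.equal(object@muMax, max(object@values))))
    msgs <- c(msgs, "muMin/muMax must equal the extremes of the stored values")
  if (length(msgs)) msgs else TRUE
})

ReferenceSignal <- function(times, values, periodic = TRUE, metadata = list()) {
  new("ReferenceSignal", times = as.numeric(times), values = as.numeric(values),
      muMin = min(values), muMax = max(values), periodic = periodic,
      metadata = metadata)
}

#' @rdname muRange
#' @export
setMethod("muRange", "ReferenceSignal", function(x) c(x@muMin, x@muMax))

#' Constant reference signal
#'
#' Convenience constructor for set-point tracking experiments (the abstract
#' one-species plant mode).
#'
#' @param value the constant set point (>= 0).
#' @param horizon time horizon covered (h).
#' @return A \code{ReferenceSignal} evaluating to \code{value} everywhere
#'   in \code{[0, horizon]}.
#' @export
constantReference <- function(value, horizon = 1e6) {
  ReferenceSignal(times = c(0, horizon), values = c(value, value),
                  periodic = FALSE, metadata = list(constant = TRUE))
}

#' Clock design metadata
#'
#' Identifies, for a packaged clock model, which gene is the control target,
#' which positive regulator is lost under the perturbation, and the linear
#' degradation rate of the target used by the sequestration-rate bound.
#'
#' @slot modelId one of JL2005, JD2016, HU2001, SB2004, AD2015.
#' @slot targetSpecies the controlled gene.
#' @slot lostRegulator the positive regulator removed by the perturbation.
#' @slot gammaP linear degradation rate of the target species (1/h); 0 for
#'   a pure-integrator target with no degradation.
#' @slot publishedMuRange published extremes (min, max) of the target's
#'   reference profile; used as calibration targets and design inputs.
#' @slot parameterSource provenance string.
#' @export
setClass("ClockModelSpec", representation(
  modelId = "character", targetSpecies = "character",
  lostRegulator = "character", gammaP = "numeric",
  publishedMuRange = "numeric", parameterSource = "character"
))

.clockTriples <- data.frame(
  modelId       = c("JL2005", "JD2016", "HU2001", "SB2004", "AD2015"),
  targetSpecies = c("LHY_CCA1", "HYP", "PER", "BMAL1", "FRQ"),
  lostRegulator = c("TOC1", "PIF", "CLK_CYC", "PER2_CRY", "WC1"),
  stringsAsFactors = FALSE
)

setValidity("ClockModelSpec", function(object) {
  msgs <- character(0)
  row <- .clockTriples[.clockTriples$modelId == object@modelId, ]
  if (nrow(row) == 1L) {
    if (!identical(object@targetSpecies, row$targetSpecies) ||
        !identical(object@lostRegulator, row$lostRegulator))
      msgs <- c(msgs, sprintf(
        "(%s) target/lost-regulator pair must be (%s, %s)",
        object@modelId, row$targetSpecies, row$lostRegulator))
    if (object@modelId == "JD2016" && object@gammaP != 0)
      msgs <- c(msgs, "JD2016 target (HYP) has no degradation: gammaP must be 0")
  }
  if (length(object@gammaP) != 1L || !is.finite(object@gammaP) || object@gammaP < 0)
    msgs <- c(msgs, "gammaP must be a single finite nonnegative rate")
  if (length(msgs)) msgs else TRUE
})

ClockModelSpec <- function(modelId, targetSpecies, lostRegulator, gammaP,
                           publishedMuRange = c(NA_real_, NA_real_),
                           parameterSource = "user") {
  new("ClockModelSpec", modelId = modelId, targetSpecies = targetSpecies,
      lostRegulator = lostRegulator, gammaP = as.numeric(gammaP),
      publishedMuRange = as.numeric(publishedMuRange),
      parameterSource = parameterSource)
}

#' Antithetic integral feedback controller parameters
#'
#' The two-species sequestration controller has an actuator species Z1
#' (produced at the reference rate mu, consumed by sequestration with Z2)
#' and a sensor species Z2 (produced by sensing the output at rate theta2).
#' Z1 actuates the plant at rate theta1; both controller species are
#' degraded at rate gammaC; mutual sequestration proceeds at rate eta.
#'
#' @slot eta sequestration (annihilation) rate, 1/(nM h).
#' @slot theta1 actuation rate, 1/h.
#' @slot theta2 sensing rate, 1/h.
#' @slot gammaC controller degradation rate, 1/h (0 for pure integral
#'   action).
#' @export
setClass("AIFParameters", representation(
  eta = "numeric", theta1 = "numeric", theta2 = "numeric", gammaC = "numeric"
))

setValidity("AIFParameters", function(object) {
  v <- c(eta = object@eta, theta1 = object@theta1,
         theta2 = object@theta2, gammaC = object@gammaC)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    return("eta, theta1, theta2 and gammaC must all be finite and >= 0")
  TRUE
})

#' @param eta,theta1,theta2,gammaC controller rates (see slots).
#' @rdname AIFParameters-class
#' @export
AIFParameters <- function(eta, theta1 = 1, theta2 = 1, gammaC = 0) {
  new("AIFParameters", eta = as.numeric(eta), theta1 = as.numeric(theta1),
      theta2 = as.numeric(theta2), gammaC = as.numeric(gammaC))
}

#' Closed-loop system: perturbed plant plus AIF controller
#'
#' Couples a perturbed clock model (or the abstract one-species linear
#' plant) to the antithetic controller. The augmented state is
#' \code{(plant species..., z1, z2)}. In the embedded mode the target
#' species receives the actuation term \code{theta1 * z1} in place of its
#' lost production; in the abstract mode the plant is
#' \code{dx1/dt = theta1 z1 - gammaP x1}.
#'
#' @slot plant perturbed \code{SSystemModel}, or \code{NULL} for the
#'   abstract one-species mode.
#' @slot targetSpecies name of the controlled output species x1.
#' @slot params \code{AIFParameters}.
#' @slot reference \code{ReferenceSignal} mu(t).
#' @slot plantInit named numeric initial plant state.
#' @slot controllerInit numeric length 2, (z1(0), z2(0)).
#' @slot gammaP degradation rate for the abstract plant mode.
#' @slot schedule \code{LightSchedule} driving the plant (or \code{NULL}).
#' @export
setClass("ClosedLoopSystem", representation(
  plant = "ANY", targetSpecies = "character", params = "AIFParameters",
  reference = "ReferenceSignal", plantInit = "numeric",
  controllerInit = "numeric", gammaP = "numeric", schedule = "ANY"
))

setValidity("ClosedLoopSystem", function(object) {
  msgs <- character(0)
  if (!is.null(object@plant)) {
    if (!is(object@plant, "SSystemModel")) msgs <- c(msgs, "plant must be an SSystemModel or NULL")
    else {
      if (!object@targetSpecies %in% object@plant@species)
        msgs <- c(msgs, sprintf("target species '%s' not in plant", object@targetSpecies))
      if (length(object@plantInit) != length(object@plant@species))
        msgs <- c(msgs, "plantInit length must match plant species count")
    }
  } else if (length(object@plantInit) != 1L) {
    msgs <- c(msgs, "abstract mode uses a single plant state x1")
  }
  if (length(object@controllerInit) != 2L || any(object@controllerInit < 0))
    msgs <- c(msgs, "controllerInit must be two nonnegative values (z1(0), z2(0))")
  if (any(object@plantInit < 0)) msgs <- c(msgs, "plant initial state must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Reference-tracking error metric
#'
#' Mean square error between the reference profile and the controlled
#' output over a fixed evaluation grid (hourly samples t = 1..96 by
#' default).
#'
#' @slot mse the mean square error (nM^2).
#' @slot nPoints number of grid points N_T.
#' @slot grid the evaluation times (h).
#' @export
setClass("TrackingMetric", representation(
  mse = "numeric", nPoints = "integer", grid = "numeric"
))

#' Parameter-sweep result
#'
#' MSE values of closed-loop runs over a grid of one controller parameter,
#' all other parameters held fixed.
#'
#' @slot parameterName one of eta, theta1, theta2, gammaC.
#' @slot grid strictly increasing parameter grid.
#' @slot mse MSE per grid value (NA for failed runs).
#' @slot optimum list(value =, mse =): smallest parameter value within 1\%
#'   of the minimal MSE.
#' @slot fixedParams \code{AIFParameters} snapshot of the non-swept
#'   parameters.
#' @slot metadata list (eta rule used, model id, timing).
#' @export
setClass("SweepResult", representation(
  parameterName = "character", grid = "numeric", mse = "numeric",
  optimum = "list", fixedParams = "AIFParameters", metadata = "list"
))

setValidity("SweepResult", function(object) {
  msgs <- character(0)
  if (!object@parameterName %in% c("eta", "theta1", "theta2", "gammaC"))
    msgs <- c(msgs, "parameterName must be one of eta, theta1, theta2, gammaC")
  if (any(diff(object@grid) <= 0)) msgs <- c(msgs, "grid must be strictly increasing")
  if (length(object@grid) != length(object@mse))
    msgs <- c(msgs, "grid and mse must have equal length")
  ok <- is.finite(object@mse)
  if (any(object@mse[ok] < 0)) msgs <- c(msgs, "mse values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Controller design report
#'
#' Record of the five-step tuning procedure: the sequestration bound, the
#' chosen controller parameters, the final tracking error and an ordered
#' step log.
#'
#' @slot modelId clock model identifier.
#' @slot etaBar the sequestration bound (NA when undefined, i.e. gammaP = 0).
#' @slot chosen \code{AIFParameters} finally selected.
#' @slot finalMSE tracking MSE of the designed controller.
#' @slot stepLog ordered list describing steps 1-5.
#' @export
setClass("DesignReport", representation(
  modelId = "character", etaBar = "numeric", chosen = "AIFParameters",
  finalMSE = "numeric", stepLog = "list"
))
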