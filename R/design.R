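## Grids used by the five-step design procedure. Kept at a resolution that
## resolves the published optima (log-spaced, 25 points over the two-decade
## range used with pure integral action, 31 points over the six-decade
## range explored with controller degradation).
.theta1GridZero  <- function() 10^seq(-1, 1, length.out = 25)
.theta1GridNonz  <- function() 10^seq(-1, 5, length.out = 31)
.gammaCGrid      <- c(0, 0.5, 1, 1.5, 2, 3, 5)

## Modify one controller parameter; with the "track" eta rule the
## sequestration rate follows the design prescription eta = 10 etaBar
## evaluated at the *current* theta1/theta2 (the bound scales as
## (theta1 theta2)^2, so a swept actuation rate moves the bound with it).
.applyParam <- function(params, name, value, etaRule, gammaP, muMin) {
  slot(params, name) <- value
  if (identical(etaRule, "track") && name %in% c("theta1", "theta2") &&
      is.finite(gammaP) && gammaP > 0) {
    params@eta <- 10 * etaBar(params@theta1, params@theta2, gammaP, muMin)
  }
  params
}

#' Choose the sequestration rate
#'
#' Implements the design prescription for the sequestration rate: when the
#' target species has a nonzero degradation rate the bound
#' \code{\link{etaBar}} is defined and \code{10 * etaBar} is returned.
#' When \code{gammaP = 0} (pure-integrator target) the bound is undefined;
#' a coarse closed-loop sweep over \code{etaGrid} is run instead, the
#' transition point located as the largest drop in log10(MSE) between
#' adjacent grid values, and 10 times the grid value at the foot of that
#' drop is returned.
#'
#' @param spec a \code{ClockModelSpec}.
#' @param reference the clock's \code{ReferenceSignal}.
#' @param theta1,theta2 actuation and sensing rates at which to evaluate
#'   the bound.
#' @param cls a \code{ClosedLoopSystem} (required for the
#'   \code{gammaP = 0} sweep path).
#' @param etaGrid sweep grid for the transition heuristic.
#' @return The chosen sequestration rate (1/(nM h)).
#' @export
chooseEta <- function(spec, reference, theta1 = 1, theta2 = 1, cls = NULL,
                      etaGrid = 10^seq(0, 3, length.out = 13)) {
  stopifnot(is(spec, "ClockModelSpec"), is(reference, "ReferenceSignal"))
  if (reference@muMin <= 0) stop("reference must have muMin > 0")
  if (spec@gammaP > 0)
    return(10 * etaBar(theta1, theta2, spec@gammaP, reference@muMin))
  if (is.null(cls))
    stop("gammaP = 0: a ClosedLoopSystem is required for the transition sweep")
  sw <- sweepParameter(cls, "eta", etaGrid)
  lm <- log10(pmax(sw@mse, 1e-300))
  drops <- -diff(lm)
  if (!any(is.finite(drops)) || max(drops, na.rm = TRUE) < 0.5)
    stop("no MSE transition found over the eta grid (flat curve)")
  transition <- sw@grid[which.max(drops) + 1L]
  10 * transition
}

#' Sweep one controller parameter
#'
#' Runs one closed-loop simulation and tracking-MSE evaluation per grid
#' value of the named parameter, all other parameters held at their values
#' in \code{cls}. Individual run failures are recorded as missing points,
#' not errors. The optimum is the smallest parameter value whose MSE is
#' within 1\% of the minimum (ties broken toward weaker actuation).
#'
#' @param cls a \code{ClosedLoopSystem} providing plant, reference and the
#'   fixed parameters.
#' @param name one of \code{"eta"}, \code{"theta1"}, \code{"theta2"},
#'   \code{"gammaC"}.
#' @param grid strictly increasing, nonempty parameter grid.
#' @param etaRule \code{"fixed"} keeps eta at its value in \code{cls};
#'   \code{"track"} re-evaluates \code{eta = 10 etaBar(theta1, theta2,
#'   gammaP, muMin)} at every swept theta1/theta2 (requires \code{gammaP}).
#' @param gammaP,muMin inputs to the bound under the \code{"track"} rule;
#'   \code{muMin} defaults to the reference floor.
#' @param tSpan,outputGrid,mseGrid simulation window, recording grid and
#'   MSE evaluation grid.
#' @return A \code{SweepResult}.
#' @export
sweepParameter <- function(cls, name, grid, etaRule = c("fixed", "track"),
                           gammaP = NA_real_, muMin = NULL,
                           tSpan = c(0, 96),
                           outputGrid = seq(tSpan[1], tSpan[2], by = 0.5),
                           mseGrid = 1:96) {
  stopifnot(is(cls, "ClosedLoopSystem"), length(grid) >= 1)
  if (any(diff(grid) <= 0)) stop("parameter grid must be strictly increasing")
  etaRule <- match.arg(etaRule)
  if (is.null(muMin)) muMin <- cls@reference@muMin
  mses <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    p <- .applyParam(cls@params, name, grid[i], etaRule, gammaP, muMin)
    cl2 <- cls; cl2@params <- p
    tr <- try(simulateClosedLoop(cl2, tSpan, outputGrid), silent = TRUE)
    if (inherits(tr, "try-error")) next
    mses[i] <- mse(trackingMSE(cls@reference, tr, cls@targetSpecies, mseGrid))
  }
  ok <- which(is.finite(mses))
  if (!length(ok)) stop("every sweep run failed")
  mmin <- min(mses[ok])
  cand <- ok[mses[ok] <= mmin * 1.01 + 1e-300]
  new("SweepResult", parameterName = name, grid = as.numeric(grid),
      mse = mses,
      optimum = list(value = grid[min(cand)], mse = mses[min(cand)]),
      fixedParams = cls@params,
      metadata = list(etaRule = etaRule, nFailed = sum(!is.finite(mses))))
}

## Build the standard closed loop for a packaged clock: perturb the model,
## start the plant on the unperturbed entrained cycle at dawn (or the
## stored state for non-periodic clocks) and the controller empty.
.clockLoop <- function(cl, ref, params) {
  spec <- cl$spec
  pert <- applyLossOfFunction(cl$model, spec@targetSpecies, spec@lostRegulator)
  trans <- (cl$model@metadata$reference$transient_days) %||% 2
  init <- if (trans > 0) {
    tr <- entrainedCycle(cl$model, LightSchedule(12), transientDays = trans,
                         recordDays = 1, dt = 1)
    setNames(tr@values[1, ], colnames(tr@values))
  } else cl$model@initial
  closedLoop(pert, spec@targetSpecies, params, ref,
             schedule = LightSchedule(12), plantInit = init)
}

#' Tracking error of the uncontrolled perturbed clock
#'
#' Simulates the perturbed model without any controller from the entrained
#' initial state and measures its MSE against the reference profile --
#' the baseline any designed controller must beat.
#'
#' @param model clock id, config path, or a \code{loadClock} result.
#' @return The uncontrolled MSE (hourly grid, t = 1..96).
#' @export
uncontrolledMSE <- function(model) {
  cl <- if (is.list(model)) model else loadClock(model)
  ref <- clockReference(cl)
  loop <- .clockLoop(cl, ref, AIFParameters(eta = 0, theta1 = 0, theta2 = 0))
  tr <- simulateClosedLoop(loop, c(0, 96), seq(0, 96, by = 0.5))
  mse(trackingMSE(ref, tr, cl$spec@targetSpecies))
}

#' Five-step controller design
#'
#' Automates the tuning procedure for a packaged clock:
#' \enumerate{
#'  \item load the clock, extract its reference profile, apply the
#'    loss-of-function perturbation and build the closed loop;
#'  \item choose the sequestration rate \code{eta = 10 etaBar} (or, for a
#'    degradation-free target, 10 times the MSE transition point);
#'  \item fix the sensing rate \code{theta2 = 1};
#'  \item set the controller degradation per \code{gammaCPolicy}:
#'    \code{"zero"}, a \code{"fixed"} value, or \code{"auto"} -- the
#'    largest degradation rate on \code{c(0, 0.5, 1, 1.5, 2, 3, 5)} whose
#'    MSE stays at or below the acceptable level 0.3;
#'  \item sweep the actuation rate theta1 (log grid; 0.1-10 for zero
#'    degradation, 0.1-1e5 otherwise; eta stays at its step-2 value by
#'    default, see \code{etaRule}) and select the optimum.
#' }
#'
#' @param model clock id or config path.
#' @param gammaCPolicy one of \code{"zero"}, \code{"fixed"}, \code{"auto"}.
#' @param gammaC the degradation rate for the \code{"fixed"} policy.
#' @param etaRule passed to the theta1 sweep (default \code{"track"}).
#' @param mseAcceptable acceptable-MSE level used by the \code{"auto"}
#'   policy.
#' @return A \code{DesignReport}.
#' @export
designController <- function(model, gammaCPolicy = c("zero", "fixed", "auto"),
                             gammaC = NULL, etaRule = "fixed",
                             mseAcceptable = 0.3) {
  gammaCPolicy <- match.arg(gammaCPolicy)
  cl <- if (is.list(model)) model else loadClock(model)
  spec <- cl$spec
  log_ <- list()
  ref <- clockReference(cl)
  log_$step1 <- list(action = "load + perturb + close loop",
                     model = spec@modelId, target = spec@targetSpecies,
                     lost = spec@lostRegulator,
                     muRange = muRange(ref))
  eb <- if (spec@gammaP > 0) etaBar(1, 1, spec@gammaP, ref@muMin) else NA_real_
  params <- AIFParameters(eta = 1, theta1 = 1, theta2 = 1, gammaC = 0)
  loop <- .clockLoop(cl, ref, params)
  eta <- if (is.finite(eb)) 10 * eb else chooseEta(spec, ref, cls = loop)
  loop@params@eta <- eta
  log_$step2 <- list(action = "sequestration rate", etaBar = eb, eta = eta)
  log_$step3 <- list(action = "sensing rate", theta2 = 1)

  ## zero-degradation theta1 optimum (also the operating point for the
  ## gammaC scan of the auto policy)
  sw0 <- sweepParameter(loop, "theta1", .theta1GridZero(), etaRule = etaRule,
                        gammaP = spec@gammaP)
  theta1Zero <- sw0@optimum$value

  gC <- switch(gammaCPolicy,
    zero = 0,
    fixed = { stopifnot(!is.null(gammaC)); gammaC },
    auto = {
      lp <- loop
      lp@params <- .applyParam(lp@params, "theta1", theta1Zero, etaRule,
                               spec@gammaP, ref@muMin)
      swg <- sweepParameter(lp, "gammaC", .gammaCGrid)
      okv <- swg@grid[is.finite(swg@mse) & swg@mse <= mseAcceptable]
      if (!length(okv)) 0 else max(okv)
    })
  log_$step4 <- list(action = "controller degradation", policy = gammaCPolicy,
                     gammaC = gC)

  loop@params@gammaC <- gC
  sw <- if (gC == 0) sw0 else
    sweepParameter(loop, "theta1", .theta1GridNonz(), etaRule = etaRule,
                   gammaP = spec@gammaP)
  theta1 <- sw@optimum$value
  log_$step5 <- list(action = "theta1 sweep", etaRule = etaRule,
                     grid = range(sw@grid), optimum = sw@optimum)

  final <- .applyParam(loop@params, "theta1", theta1, etaRule,
                       spec@gammaP, ref@muMin)
  loop@params <- final
  tr <- simulateClosedLoop(loop, c(0, 96), seq(0, 96, by = 0.5))
  fm <- mse(trackingMSE(ref, tr, spec@targetSpecies))
  new("DesignReport", modelId = spec@modelId, etaBar = eb, chosen = final,
      finalMSE = fm, stepLog = log_)
}
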