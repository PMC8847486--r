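#' Extract a reference circadian profile from a clock model
#'
#' Simulates the unperturbed model to its entrained state and samples the
#' target species on a fine grid over the requested window, producing the
#' target profile mu(t) for controller design together with its extremes.
#'
#' @param model an \code{SSystemModel} (unperturbed).
#' @param targetSpecies species whose profile becomes the reference.
#' @param windowHours length of the reference window (default 96 h).
#' @param schedule light schedule (12L:12D by default).
#' @param dt fine sampling step (default 0.1 h); linear interpolation
#'   between samples avoids overshoot at sharp circadian peaks.
#' @param transientDays days discarded before the window opens; use 0 for
#'   non-periodic targets that must start from the stored initial state.
#' @param periodic whether 24 h periodic extension of the profile is
#'   allowed (FALSE for monotone, non-oscillatory targets).
#' @return A \code{ReferenceSignal} with times re-zeroed to the window
#'   start (dawn).
#' @export
referenceProfile <- function(model, targetSpecies, windowHours = 96,
                             schedule = LightSchedule(12), dt = 0.1,
                             transientDays = 2, periodic = TRUE) {
  stopifnot(is(model, "SSystemModel"))
  if (!targetSpecies %in% model@species)
    stop(sprintf("unknown target species '%s'", targetSpecies))
  tr <- entrainedCycle(model, schedule, transientDays = transientDays,
                       recordDays = ceiling(windowHours / 24), dt = dt)
  keep <- tr@times <= windowHours + 1e-9
  ReferenceSignal(tr@times[keep], tr@values[keep, targetSpecies],
                  periodic = periodic,
                  metadata = list(model_id = model@metadata$model_id,
                                  target = targetSpecies,
                                  window_hours = windowHours,
                                  entrained = tr@metadata$entrained))
}

#' Evaluate a reference signal
#'
#' Piecewise-linear interpolation of the stored samples; values at sample
#' times are reproduced exactly. Times outside the stored window are
#' wrapped by 24 h periodicity when the signal is periodic (the result
#' then carries attribute \code{wrapped = TRUE}); for non-periodic signals
#' they are an error.
#'
#' @param ref a \code{ReferenceSignal}.
#' @param t evaluation time(s), h.
#' @return Numeric vector of mu values.
#' @export
evaluateReference <- function(ref, t) {
  stopifnot(is(ref, "ReferenceSignal"))
  t0 <- ref@times[1]; t1 <- ref@times[length(ref@times)]
  outside <- t < t0 - 1e-9 | t > t1 + 1e-9
  if (any(outside)) {
    if (!ref@periodic)
      stop(sprintf("t = %g outside the reference window [%g, %g] and periodic wrapping is disabled",
                   t[which(outside)[1]], t0, t1))
    t[outside] <- t0 + (t[outside] - t0) %% 24
  }
  out <- stats::approx(ref@times, ref@values, xout = t, rule = 2)$y
  if (any(outside)) attr(out, "wrapped") <- TRUE
  out
}

## Fast closure form used inside ODE right-hand sides.
.referenceFun <- function(ref) {
  f <- stats::approxfun(ref@times, ref@values, rule = 2)
  t0 <- ref@times[1]; t1 <- ref@times[length(ref@times)]
  if (ref@periodic) {
    function(t) f(if (t > t1 || t < t0) t0 + (t - t0) %% 24 else t)
  } else f
}
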