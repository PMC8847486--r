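setMethod("show", "LightSchedule", function(object) {
  p <- object@photoperiod
  lab <- if (p == 0) "DD (constant dark)" else if (p == 24) "LL (constant light)"
         else sprintf("%gL:%gD", p, 24 - p)
  cat(sprintf("LightSchedule: %s, 24 h cycle, dawn at t = 0\n", lab))
})

setMethod("show", "SSystemModel", function(object) {
  n <- length(object@species)
  nterms <- function(sl) sum(lengths(sl))
  cat(sprintf("SSystemModel%s with %d species: %s\n",
              if (!is.null(object@metadata$model_id))
                paste0(" '", object@metadata$model_id, "'") else "",
              n, paste(object@species, collapse = ", ")))
  cat(sprintf("  production factors: %d | degradation terms: %d | light terms: %d\n",
              sum(vapply(object@production, function(p) length(p$factors), 0L)),
              nterms(object@degradation), nterms(object@light)))
  if (!is.null(object@metadata$lost))
    cat(sprintf("  perturbed: lost %s input to %s\n",
                object@metadata$lost$factor, object@metadata$lost$target))
  if (!is.null(object@metadata$design))
    cat(sprintf("  design target: %s (lost regulator %s)\n",
                object@metadata$design@targetSpecies,
                object@metadata$design@lostRegulator))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples over [%g, %g] h, series: %s\n",
              length(object@times), min(object@times), max(object@times),
              paste(colnames(object@values), collapse = ", ")))
  if (!is.null(object@metadata$nclip) && object@metadata$nclip > 0)
    cat(sprintf("  %d recorded values clipped at 0\n", object@metadata$nclip))
})

setMethod("show", "ReferenceSignal", function(object) {
  cat(sprintf("ReferenceSignal: mu in [%.4f, %.4f] over [%g, %g] h (%s)\n",
              object@muMin, object@muMax, min(object@times), max(object@times),
              if (object@periodic) "24 h periodic extension allowed"
              else "non-periodic"))
})

setMethod("show", "ClockModelSpec", function(object) {
  cat(sprintf("ClockModelSpec %s: control %s, lost regulator %s, gammaP = %g /h\n",
              object@modelId, object@targetSpecies, object@lostRegulator,
              object@gammaP))
  if (all(is.finite(object@publishedMuRange)))
    cat(sprintf("  published reference range: (%.4f, %.4f)\n",
                object@publishedMuRange[1], object@publishedMuRange[2]))
})

setMethod("show", "AIFParameters", function(object) {
  cat(sprintf("AIFParameters: eta = %g /(nM h), theta1 = %g /h, theta2 = %g /h, gammaC = %g /h\n",
              object@eta, object@theta1, object@theta2, object@gammaC))
})

setMethod("show", "ClosedLoopSystem", function(object) {
  cat(sprintf("ClosedLoopSystem (%s plant), output %s\n",
              if (is.null(object@plant)) "abstract 1-species"
              else sprintf("%d-species", length(object@plantInit)),
              object@targetSpecies))
  show(object@params)
})

setMethod("show", "TrackingMetric", function(object) {
  cat(sprintf("TrackingMetric: MSE = %.6g over %d points\n",
              object@mse, object@nPoints))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s over [%g, %g] (%d points), min MSE = %.4g at %s = %g\n",
              object@parameterName, min(object@grid), max(object@grid),
              length(object@grid), object@optimum$mse, object@parameterName,
              object@optimum$value))
})

setMethod("show", "DesignReport", function(object) {
  cat(sprintf("DesignReport for %s\n", object@modelId))
  cat(sprintf("  etaBar: %s\n", if (is.finite(object@etaBar))
    sprintf("%.4f", object@etaBar) else "undefined (gammaP = 0)"))
  show(object@chosen)
  cat(sprintf("  final MSE: %.6g\n", object@finalMSE))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective %.4g after %d iterations (%s)\n",
              object@objectiveValue, object@iterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "EstimationProblem", function(object) {
  cat(sprintf("EstimationProblem: %d species x %d time points, %d free parameters\n",
              ncol(object@training@values), nrow(object@training@values),
              nrow(object@free)))
})

#' Plot a trajectory or sweep
#'
#' @param x a \code{Trajectory} or \code{SweepResult}.
#' @param y ignored.
#' @param ... passed to \code{matplot}/\code{plot}.
#' @export
setMethod("plot", signature(x = "Trajectory", y = "missing"),
          function(x, y, ...) {
  graphics::matplot(x@times, x@values, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration (nM)", ...)
  graphics::legend("topright", legend = colnames(x@values),
                   col = seq_len(ncol(x@values)), lty = 1, bty = "n")
  invisible(x)
})

#' @rdname plot-Trajectory-missing-method
#' @export
setMethod("plot", signature(x = "SweepResult", y = "missing"),
          function(x, y, ...) {
  graphics::plot(x@grid, x@mse, log = "xy", type = "b", pch = 16,
                 xlab = x@parameterName, ylab = "MSE", ...)
  graphics::abline(v = x@optimum$value, lty = 3)
  invisible(x)
})
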