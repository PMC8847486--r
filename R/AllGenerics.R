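#' @import methods
NULL

#' Species names of a model or trajectory
#'
#' @param x an \code{SSystemModel} or \code{Trajectory}.
#' @return Character vector of species identifiers, in model order.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Reference profile extremes
#'
#' @param x a \code{ReferenceSignal}.
#' @return Numeric vector \code{c(min, max)} of the stored profile.
#' @export
setGeneric("muRange", function(x) standardGeneric("muRange"))
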