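#' Evaluate the square-wave light signal
#'
#' Returns 1 during the light interval of each 24 h cycle (dawn at t = 0)
#' and 0 otherwise: \code{L(t) = 1} iff \code{0 <= t mod 24 < photoperiod}.
#'
#' @param schedule a \code{LightSchedule}.
#' @param t time(s) in hours; may be negative (periodic extension).
#' @return Integer vector of 0/1 values, one per element of \code{t}.
#' @examples
#' lightSignal(LightSchedule(12), c(5, 13, 37))
#' lightSignal(LightSchedule(0), 10)   # constant dark
#' @export
lightSignal <- function(schedule, t) {
  stopifnot(is(schedule, "LightSchedule"), all(is.finite(t)))
  tm <- t %% 24
  as.integer(tm < schedule@photoperiod)
}

## Light on/off transition times intersecting [t0, t1], used to split the
## integration so the discontinuous forcing is seen exactly.
.lightTransitions <- function(schedule, t0, t1) {
  p <- schedule@photoperiod
  offsets <- unique(c(0, p %% 24))
  ks <- seq(floor(t0 / 24) - 1, ceiling(t1 / 24) + 1)
  tt <- sort(unique(as.vector(outer(ks * 24, offsets, `+`))))
  tt[tt > t0 & tt < t1]
}
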