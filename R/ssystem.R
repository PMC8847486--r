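## Nonnegativity floor applied to the state before any power evaluation:
## non-integer powers of negative numbers are undefined and concentrations
## are physically nonnegative.
.CLIP_FLOOR <- 1e-9

## Compile a model into an index-based structure for fast RHS evaluation.
.compileModel <- function(model) {
  sp <- model@species
  idx <- function(nms) match(nms, sp)
  n <- length(sp)
  prod <- vector("list", n); deg <- vector("list", n); lig <- vector("list", n)
  for (i in seq_len(n)) {
    p <- model@production[[i]]
    prod[[i]] <- list(
      alpha = p$alpha,
      fid = lapply(p$factors, function(f) idx(f$members)),
      g = vapply(p$factors, function(f) f$exponent, numeric(1))
    )
    deg[[i]] <- lapply(model@degradation[[i]], function(d) {
      k <- idx(names(d$exponents))
      keep <- which(d$exponents != 0)
      list(beta = d$beta, k = k[keep], h = unname(d$exponents[keep]))
    })
    lig[[i]] <- lapply(model@light[[i]], function(l) {
      list(gamma = l$gamma, light = identical(l$gate, "light"),
           fid = if (is.null(l$factor)) NULL else idx(l$factor$members),
           g = if (is.null(l$factor)) NA_real_ else l$factor$exponent)
    })
  }
  list(n = n, species = sp, prod = prod, deg = deg, light = lig,
       floor = .CLIP_FLOOR)
}

## Raw RHS on a compiled model; x is clipped to the floor first, L in {0,1}.
.ssDeriv <- function(x, L, C) {
  x <- pmax(x, C$floor)
  dx <- numeric(C$n)
  for (i in seq_len(C$n)) {
    p <- C$prod[[i]]
    pr <- p$alpha
    if (pr != 0) {
      for (f in seq_along(p$fid)) {
        pr <- pr * sum(x[p$fid[[f]]])^p$g[f]
      }
    }
    d <- 0
    dl <- C$deg[[i]]
    for (j in seq_along(dl)) {
      dd <- dl[[j]]
      term <- dd$beta * x[i]
      if (length(dd$k)) term <- term * prod(x[dd$k]^dd$h)
      d <- d + term
    }
    l <- 0
    ll <- C$light[[i]]
    for (j in seq_along(ll)) {
      lt <- ll[[j]]
      gate <- if (lt$light) L else 1 - L
      if (gate != 0) {
        term <- lt$gamma
        if (!is.null(lt$fid)) term <- term * sum(x[lt$fid])^lt$g
        l <- l + term
      }
    }
    dx[i] <- pr - d + l
  }
  dx
}

#' Evaluate the extended S-System right-hand side
#'
#' Computes dX/dt for every species: the production block minus the sum of
#' degradation terms plus the sum of light-coupled terms, at the given
#' state and time. State components are clipped to a floor of 1e-9 nM
#' before power evaluation.
#'
#' @param model an \code{SSystemModel}.
#' @param state nonnegative numeric state vector (model species order).
#' @param t time in hours (used only through the light signal).
#' @param schedule a \code{LightSchedule}.
#' @return Named numeric vector of derivatives (nM/h).
#' @examples
#' m <- SSystemModel("X", production = list(X = list(alpha = 2)),
#'                   degradation = list(X = list(list(beta = 1, exponents = c()))))
#' ssDerivative(m, 1, 0, LightSchedule(12))  # 2 - 1*1 = 1
#' @export
ssDerivative <- function(model, state, t = 0, schedule = LightSchedule(12)) {
  stopifnot(is(model, "SSystemModel"))
  if (length(state) != length(model@species))
    stop("state length must equal the number of species")
  C <- .compileModel(model)
  dx <- .ssDeriv(as.numeric(state), lightSignal(schedule, t), C)
  bad <- which(!is.finite(dx))
  if (length(bad))
    stop(sprintf("non-finite derivative for species %s (invalid exponent/state combination)",
                 paste(model@species[bad], collapse = ", ")))
  setNames(dx, model@species)
}

#' Remove a lost positive regulation from a model
#'
#' Models a loss-of-function perturbation: the selected positive-regulation
#' production contribution of the target species is permanently zeroed
#' (the production block's rate constant is set to 0, so the contribution
#' vanishes at every state). All other terms -- including negative
#' regulation acting through degradation cofactors, and direct light
#' coupling -- are untouched.
#'
#' @param model an \code{SSystemModel}.
#' @param targetSpecies the species losing its positive input.
#' @param lostFactor either the name of a regulator species appearing (as a
#'   member, with positive exponent) in a production factor of the target,
#'   or \code{"block"} to zero the whole production block explicitly, or
#'   \code{NULL} for a no-op (identity) copy.
#' @return A perturbed copy of \code{model}; the lost regulation is
#'   recorded in \code{metadata$lost}.
#' @export
applyLossOfFunction <- function(model, targetSpecies, lostFactor = "block") {
  stopifnot(is(model, "SSystemModel"))
  if (!targetSpecies %in% model@species)
    stop(sprintf("unknown target species '%s'", targetSpecies))
  if (is.null(lostFactor)) return(model)
  p <- model@production[[targetSpecies]]
  if (!identical(lostFactor, "block")) {
    hit <- vapply(p$factors, function(f)
      lostFactor %in% f$members && f$exponent > 0, logical(1))
    if (!any(hit)) {
      avail <- unlist(lapply(p$factors, function(f)
        if (f$exponent > 0) f$members else character(0)))
      stop(sprintf(
        "'%s' is not a positive-regulation production factor of %s; available: %s",
        lostFactor, targetSpecies,
        if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
    }
  }
  p$alpha <- 0
  model@production[[targetSpecies]] <- p
  model@metadata$lost <- list(target = targetSpecies, factor = lostFactor)
  validObject(model)
  model
}
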