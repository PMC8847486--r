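## Model config dialect: one YAML document per model. Top-level keys:
## species, initial_state, production, degradation, light, units, model_id,
## design (optional controller-design metadata). Rate constants must be
## nonnegative; every species reference must resolve.

.collectConfigErrors <- function(doc) {
  errs <- character(0)
  err <- function(path, msg) sprintf("%s: %s", path, msg)
  if (is.null(doc$species) || length(doc$species) < 1L)
    return(err("species", "at least one species is required"))
  sp <- as.character(doc$species)
  checkMembers <- function(members, path) {
    if (is.null(members) || !length(members))
      return(err(path, "factor membership must select at least one species"))
    bad <- setdiff(as.character(members), sp)
    if (length(bad)) return(err(path, paste("unknown species:", paste(bad, collapse = ", "))))
    NULL
  }
  for (s in names(doc$production)) {
    path <- paste0("production/", s)
    if (!s %in% sp) { errs <- c(errs, err(path, "unknown species")); next }
    p <- doc$production[[s]]
    if (is.null(p$alpha) || !is.numeric(p$alpha) || p$alpha < 0)
      errs <- c(errs, err(path, "alpha must be a nonnegative number"))
    for (j in seq_along(p$factors)) {
      f <- p$factors[[j]]
      fp <- sprintf("%s/factors[%d]", path, j)
      errs <- c(errs, checkMembers(f$members, fp))
      if (is.null(f$exponent) || !is.numeric(f$exponent))
        errs <- c(errs, err(fp, "exponent must be a number"))
    }
  }
  for (s in names(doc$degradation)) {
    path <- paste0("degradation/", s)
    if (!s %in% sp) { errs <- c(errs, err(path, "unknown species")); next }
    for (j in seq_along(doc$degradation[[s]])) {
      d <- doc$degradation[[s]][[j]]
      dp <- sprintf("%s[%d]", path, j)
      if (is.null(d$beta) || !is.numeric(d$beta) || d$beta < 0)
        errs <- c(errs, err(dp, "beta must be a nonnegative number"))
      bad <- setdiff(names(d$exponents), sp)
      if (length(bad)) errs <- c(errs, err(dp, paste("unknown cofactor species:",
                                                     paste(bad, collapse = ", "))))
    }
  }
  for (s in names(doc$light)) {
    path <- paste0("light/", s)
    if (!s %in% sp) { errs <- c(errs, err(path, "unknown species")); next }
    for (j in seq_along(doc$light[[s]])) {
      l <- doc$light[[s]][[j]]
      lp <- sprintf("%s[%d]", path, j)
      if (is.null(l$gamma) || !is.numeric(l$gamma))
        errs <- c(errs, err(lp, "gamma must be a number"))
      if (is.null(l$gate) || !l$gate %in% c("light", "dark"))
        errs <- c(errs, err(lp, "gate must be 'light' or 'dark'"))
      if (!is.null(l$factor)) errs <- c(errs, checkMembers(l$factor$members,
                                                           paste0(lp, "/factor")))
    }
  }
  if (!is.null(doc$initial_state)) {
    bad <- setdiff(names(doc$initial_state), sp)
    if (length(bad)) errs <- c(errs, err("initial_state",
                                         paste("unknown species:", paste(bad, collapse = ", "))))
    v <- unlist(doc$initial_state)
    if (any(!is.finite(v)) || any(v < 0))
      errs <- c(errs, err("initial_state", "values must be finite and >= 0"))
  }
  errs[!vapply(errs, is.null, logical(1))]
}

#' Read a model configuration file
#'
#' Parses and validates a YAML model config, reporting every violation
#' with a path into the document. If the config carries a \code{design}
#' section, the resulting \code{ClockModelSpec} is attached as
#' \code{metadata$design}.
#'
#' @param path file path to a model config.
#' @return An \code{SSystemModel}.
#' @seealso \code{\link{writeModel}}, \code{\link{loadClock}}
#' @export
readModel <- function(path) {
  doc <- yaml::read_yaml(path)
  errs <- .collectConfigErrors(doc)
  if (length(errs))
    stop(paste(c(sprintf("invalid model config '%s':", path), errs), collapse = "\n  "))
  sp <- as.character(doc$species)
  init <- setNames(rep(1, length(sp)), sp)
  for (s in names(doc$initial_state)) init[[s]] <- as.numeric(doc$initial_state[[s]])
  norml <- function(terms) lapply(terms, function(tt) {
    tt$exponents <- if (length(tt$exponents)) unlist(tt$exponents) else
      setNames(numeric(0), character(0))
    tt
  })
  deg <- lapply(doc$degradation, norml)
  model <- SSystemModel(
    species = sp,
    production = doc$production,
    degradation = deg,
    light = doc$light,
    initial = init,
    units = if (!is.null(doc$units)) unlist(doc$units) else
      c(concentration = "nM", time = "h"),
    metadata = list(model_id = doc$model_id)
  )
  if (!is.null(doc$design)) {
    d <- doc$design
    model@metadata$design <- ClockModelSpec(
      modelId = d$model_id %||% doc$model_id,
      targetSpecies = d$target_species,
      lostRegulator = d$lost_regulator,
      gammaP = d$gamma_P,
      publishedMuRange = if (!is.null(d$published_mu_range))
        as.numeric(d$published_mu_range) else c(NA_real_, NA_real_),
      parameterSource = d$parameter_source %||% "config")
    model@metadata$reference <- d$reference
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a model to a configuration file
#'
#' Writes the model back to the YAML config dialect at full float
#' precision, so that parse -> serialize -> parse is the identity on the
#' semantic content.
#'
#' @param model an \code{SSystemModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "SSystemModel"))
  deg <- lapply(model@degradation, function(terms) lapply(terms, function(tt) {
    list(beta = tt$beta, exponents = as.list(tt$exponents))
  }))
  doc <- list(
    model_id = model@metadata$model_id,
    species = as.list(model@species),
    units = as.list(model@units),
    initial_state = as.list(model@initial),
    production = model@production,
    degradation = deg,
    light = model@light
  )
  d <- model@metadata$design
  if (!is.null(d)) {
    doc$design <- list(
      model_id = d@modelId, target_species = d@targetSpecies,
      lost_regulator = d@lostRegulator, gamma_P = d@gammaP,
      published_mu_range = as.list(d@publishedMuRange),
      parameter_source = d@parameterSource,
      reference = model@metadata$reference)
  }
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' Write / read trajectory tables
#'
#' Trajectories are exchanged as CSV with a mandatory header: first column
#' \code{time_h}, then one column per series (species, and z1/z2/mu for
#' augmented closed-loop runs). Floats are written with 17 significant
#' digits so the round trip is lossless.
#'
#' @param traj a \code{Trajectory}.
#' @param path file path.
#' @return \code{writeTrajectory}: \code{path}, invisibly;
#'   \code{readTrajectory}: a \code{Trajectory} (no schedule attached).
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  df <- data.frame(time_h = format(traj@times, digits = 17, trim = TRUE))
  for (j in colnames(traj@values))
    df[[j]] <- format(traj@values[, j], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(colnames(df)[1], "time_h"))
    stop("trajectory table must start with a 'time_h' column")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("trajectory table must contain numeric cells only")
  tt <- df[[1]]
  if (any(diff(tt) <= 0)) stop("time column must be strictly increasing")
  Trajectory(tt, as.matrix(df[, -1, drop = FALSE]),
             metadata = list(source = path))
}
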