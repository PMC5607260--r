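#' Stimulus condition constructor
#'
#' @param doses named numeric vector of ligand doses (nM); zero or more
#'   ligands simultaneously.  Ligand concentration is held constant over
#'   the simulation (bath application, no depletion).
#' @param times strictly increasing time grid starting at 0 (min);
#'   defaults to [defaultTimeGrid()].
#' @return list with elements `doses` and `times`.
#' @export
stimulusCondition <- function(doses = numeric(0),
                              times = defaultTimeGrid()) {
  if (length(doses) && (is.null(names(doses)) || any(doses < 0)))
    ltStop("config", "doses must be a named vector of non-negative nM")
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    ltStop("config", "times must start at 0 and increase strictly")
  list(doses = doses, times = times)
}

#' Simulate a ligand stimulation
#'
#' Integrates from the ligand-free basal steady state with the given
#' ligand doses applied at t = 0 and returns states and derived
#' phospho-observables on the requested grid.
#'
#' @param model an [RTKModel-class].
#' @param context cell line context; see [steadyState()].
#' @param doses named numeric ligand doses (nM), e.g. `c(EGF = 10)`.
#' @param times output time grid (min), starting at 0.
#' @param line optional cell line name selecting a panel row.
#' @param ss optional precomputed [steadyState()] result.
#' @param rtol,atol integrator tolerances.
#' @return a [Trajectory-class].
#' @examples
#' m <- buildModel()
#' ctx <- list(name = "demo",
#'             receptors = c(EGFR = 2e5, HER2 = 1e5, ErbB3 = 3e4,
#'                           Met = 4e4, IGF1R = 3e4))
#' tr <- simulateTrajectory(m, ctx, doses = c(EGF = 10))
#' @export
simulateTrajectory <- function(model, context, doses = numeric(0),
                               times = defaultTimeGrid(), line = NULL,
                               ss = NULL, rtol = 1e-8, atol = 1e-10) {
  stim <- stimulusCondition(doses, times)
  ctx <- cellContext(context, line)
  if (is.null(ss)) ss <- steadyState(model, ctx)
  ptr <- packParms(model, unname(ss$synthesis), stim$doses)
  activateModelCpp(ptr)
  out <- try(deSolve::lsoda(
    y = unname(ss$x0), times = stim$times,
    func = "lt_derivs", dllname = "ligandtree", initfunc = NULL,
    parms = NULL,
    rtol = rtol, atol = atol, maxsteps = 2e4), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(stim$times)) {
    tFail <- if (inherits(out, "try-error")) NA_real_
             else out[nrow(out), 1]
    ltStop("numerical", sprintf(
      "integration failed for '%s' near t = %s min", ctx$name,
      format(tFail)))
  }
  S <- out[, -1, drop = FALSE]
  colnames(S) <- model@stateNames
  new("Trajectory", time = stim$times, states = S,
      observables = observableMatrix(model, S),
      cellLine = ctx$name, doses = stim$doses)
}

#' Simulate from an arbitrary initial state
#'
#' Lower-level entry point integrating the model from a supplied state
#' vector with explicit synthesis rates (use zeros together with zeroed
#' turnover rates for conservation analyses).
#'
#' @param model an [RTKModel-class].
#' @param x0 numeric state vector of length [nStates()].
#' @param doses named numeric ligand doses (nM).
#' @param times output grid starting at 0.
#' @param synthesis per-receptor synthesis rates (molecules/cell/min).
#' @param rtol,atol integrator tolerances.
#' @return a [Trajectory-class] (cell line `"custom"`).
#' @export
simulateFromState <- function(model, x0, doses = numeric(0),
                              times = defaultTimeGrid(),
                              synthesis = rep(0, 5), rtol = 1e-8,
                              atol = 1e-10) {
  stim <- stimulusCondition(doses, times)
  if (length(x0) != nStates(model))
    ltStop("config", "x0 length does not match the state count")
  ptr <- packParms(model, synthesis, stim$doses)
  activateModelCpp(ptr)
  out <- try(deSolve::lsoda(
    y = unname(x0), times = stim$times,
    func = "lt_derivs", dllname = "ligandtree", initfunc = NULL,
    parms = NULL, rtol = rtol, atol = atol, maxsteps = 2e4),
    silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(stim$times))
    ltStop("numerical", "integration failed")
  S <- out[, -1, drop = FALSE]
  colnames(S) <- model@stateNames
  new("Trajectory", time = stim$times, states = S,
      observables = observableMatrix(model, S), cellLine = "custom",
      doses = stim$doses)
}

#' Per-receptor copy totals along a trajectory
#'
#' Total copies of each receptor: free + ligand-bound monomers plus
#' twice (homodimers) or once (heterodimers) the surface and internal
#' dimer pools.  Conserved when synthesis and all turnover rates are
#' zero.
#'
#' @param model an [RTKModel-class].
#' @param traj a [Trajectory-class] from this model.
#' @return matrix time points x receptors.
#' @export
receptorTotals <- function(model, traj) {
  st <- model@structure
  S <- traj@states
  d <- st$dimers
  out <- matrix(0, nrow(S), st$nR,
                dimnames = list(NULL, st$receptors))
  for (r in seq_len(st$nR)) {
    tot <- S[, st$iR[r] + 1L]
    b <- st$bound[st$bound$recIdx == r - 1L, , drop = FALSE]
    for (ib in b$idx) tot <- tot + S[, ib + 1L]
    for (k in seq_len(nrow(d))) {
      mult <- (d$recAi[k] == r - 1L) + (d$recBi[k] == r - 1L)
      if (mult > 0)
        tot <- tot + mult * (S[, d$iDs[k] + 1L] + S[, d$iDi[k] + 1L])
    }
    out[, r] <- tot
  }
  out
}

#' Extract an observable or state time course
#'
#' @param traj a [Trajectory-class].
#' @param species an observable name (e.g. `"pERK"`, `"pD_EGFR_HER2"`) or
#'   a state name.
#' @return numeric vector along the trajectory's time grid.
#' @export
speciesValues <- function(traj, species) {
  obs <- traj@observables
  if (species %in% colnames(obs)) return(obs[, species])
  st <- traj@states
  if (!is.null(colnames(st)) && species %in% colnames(st))
    return(st[, species])
  ltStop("schema", paste0("unknown species '", species, "'"))
}

setMethod("observableNames", "Trajectory", function(object) {
  colnames(object@observables)
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory for", object@cellLine, "\n")
  dd <- object@doses
  cond <- if (length(dd)) paste(names(dd), dd, sep = "=", collapse = ", ")
          else "unstimulated"
  cat("  condition:  ", cond, "(nM)\n")
  cat("  time points:", length(object@time), " (",
      min(object@time), "-", max(object@time), "min )\n")
  cat("  states:     ", ncol(object@states), "\n")
})

#' Write a trajectory as tidy CSV
#'
#' One row per (time, species) pair with columns `cell_line`,
#' `ligand_condition`, `time_min`, `species`, `value`.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @param what `"observables"` (default) or `"states"`.
#' @param hash optional config hash stamped as a comment header.
#' @return invisibly, the written data.frame.
#' @export
writeTrajectory <- function(traj, path, what = c("observables", "states"),
                            hash = NULL) {
  what <- match.arg(what)
  M <- if (what == "observables") traj@observables else traj@states
  dd <- traj@doses
  cond <- if (length(dd)) paste(names(dd), dd, sep = "=", collapse = "+")
          else "unstimulated"
  df <- data.frame(
    cell_line = traj@cellLine,
    ligand_condition = cond,
    time_min = rep(traj@time, ncol(M)),
    species = rep(colnames(M), each = nrow(M)),
    value = as.vector(M))
  writeCsvWithHash(df, path, hash)
  invisible(df)
}
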