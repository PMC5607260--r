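# Simulated signaling features: trapezoidal areas under the curve of the
# phosphorylated signaling dimers and of pAKT, pERK and pS6 over the
# stimulation window, plus optional fold-change and quasi-steady-state
# extras.  AUCs integrate the total (raw) phospho-level; a
# baseline-subtracted variant sits behind a flag.

#' Area under the curve of a species
#'
#' Trapezoidal integral of an observable (or state) over `[t0, t1]`,
#' with linear interpolation at the window edges if they fall between
#' grid points.
#'
#' @param traj a [Trajectory-class].
#' @param species observable or state name.
#' @param t0,t1 integration window (min); defaults to the full grid span.
#' @return non-negative scalar (for non-negative species).
#' @export
aucFeature <- function(traj, species, t0 = NULL, t1 = NULL) {
  tt <- traj@time
  t0 <- t0 %||% tt[1]
  t1 <- t1 %||% tt[length(tt)]
  if (t0 < tt[1] || t1 > tt[length(tt)] || t0 >= t1)
    ltStop("precondition",
           "[t0, t1] must lie within the trajectory grid span")
  y <- speciesValues(traj, species)
  grid <- sort(unique(c(t0, t1, tt[tt >= t0 & tt <= t1])))
  yy <- approx(tt, y, xout = grid)$y
  trapzAuc(grid, yy)
}

featureColumns <- function(model) {
  d <- model@spec@dimers
  sig <- d$signaling
  c(paste0("pD_", d$recA[sig], "_", d$recB[sig]), "pAKT", "pERK", "pS6")
}

#' Simulated feature table for a panel
#'
#' One row per (cell line, ligand) with the simulated feature set: the
#' AUC of every phosphorylated signaling dimer plus the AUC of pAKT, pERK
#' and pS6 (12 features for the 10-dimer network), the mutation flags
#' copied from the panel, and the ligand identity.  Optional extras add
#' the fold change (max over baseline) and the quasi-steady-state level
#' (value at the horizon end) of each feature species.
#'
#' @param model an [RTKModel-class].
#' @param contexts a [CellLinePanel-class].
#' @param ligands ligands to stimulate with.
#' @param doses named screen doses (nM); defaults to 5 nM EGF, 5 nM HRG,
#'   1 nM HGF, 50 nM IGF-1.
#' @param times simulation grid (min).
#' @param extras logical; add fold-change and quasi-steady-state columns.
#' @param baselineSubtract logical; subtract the basal level times the
#'   window length from each AUC.
#' @return data.frame with columns `cell_line`, `ligand`, `kras_mutant`,
#'   `pik3ca_mutant` and one `auc_*` column per feature (plus `fc_*`,
#'   `qss_*` with extras).  Rows whose simulation fails are excluded with
#'   a warning.
#' @export
featureTable <- function(model, contexts,
                         ligands = c("EGF", "HRG", "HGF", "IGF1"),
                         doses = c(EGF = 5, HRG = 5, HGF = 1, IGF1 = 50),
                         times = defaultTimeGrid(), extras = FALSE,
                         baselineSubtract = FALSE) {
  stopifnot(is(contexts, "CellLinePanel"))
  miss <- setdiff(ligands, names(doses))
  if (length(miss))
    ltStop("config", paste("no dose for ligand(s):",
                           paste(miss, collapse = ", ")))
  fcols <- featureColumns(model)
  span <- max(times) - min(times)
  rows <- list()
  for (line in cellLines(contexts)) {
    ctx <- cellContext(contexts, line)
    ss <- try(steadyState(model, ctx), silent = TRUE)
    if (inherits(ss, "try-error")) {
      warning("steady state failed for ", line, "; rows excluded")
      next
    }
    for (lg in ligands) {
      traj <- try(simulateTrajectory(model, ctx,
                                     doses = doses[lg], times = times,
                                     ss = ss), silent = TRUE)
      if (inherits(traj, "try-error")) {
        warning("simulation failed for ", line, " + ", lg,
                "; row excluded")
        next
      }
      obs <- traj@observables[, fcols, drop = FALSE]
      auc <- vapply(fcols, function(cn)
        trapzAuc(times, obs[, cn]), 0)
      if (baselineSubtract)
        auc <- pmax(auc - obs[1, ] * span, 0)
      row <- data.frame(cell_line = line, ligand = lg,
                        kras_mutant = ctx$kras_mutant,
                        pik3ca_mutant = ctx$pik3ca_mutant,
                        stringsAsFactors = FALSE)
      row[paste0("auc_", fcols)] <- as.list(unname(auc))
      if (extras) {
        base <- pmax(obs[1, ], 1e-12)
        row[paste0("fc_", fcols)] <-
          as.list(apply(obs, 2, max) / base)
        row[paste0("qss_", fcols)] <- as.list(obs[nrow(obs), ])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
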