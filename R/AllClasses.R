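#' @import methods
NULL

#' Network specification of the multi-receptor signaling model
#'
#' Declarative description of the reaction network: the five receptor
#' tyrosine kinases (EGFR, HER2, ErbB3, Met, IGF1R), the ligand-to-receptor
#' map, the list of homo- and heterodimers with a per-dimer signaling mask
#' (the ErbB3 homodimer lacks intrinsic kinase activity and cannot
#' trans-phosphorylate), and the negative-feedback links between the
#' pathways.
#'
#' @slot variant model variant; one of `"full"` (10 dimers),
#'   `"with_igf1r_heterodimers"` (12 dimers, adds EGFR:IGF1R and
#'   HER2:IGF1R) or `"no_heterodimers"` (5 homodimers, all signaling).
#' @slot receptors ordered character vector of receptor identifiers.
#' @slot ligands data.frame with columns `ligand`, `receptor`.
#' @slot dimers data.frame with columns `recA`, `recB`, `signaling`.
#' @slot feedbackLinks data.frame with columns `source`, `target`, `sign`.
#' @exportClass RTKModelSpec
setClass("RTKModelSpec",
  representation(
    variant = "character",
    receptors = "character",
    ligands = "data.frame",
    dimers = "data.frame",
    feedbackLinks = "data.frame"
  )
)

setValidity("RTKModelSpec", function(object) {
  msg <- character(0)
  d <- object@dimers
  if (!all(c("recA", "recB", "signaling") %in% names(d)))
    msg <- c(msg, "dimers must have columns recA, recB, signaling")
  else {
    if (!all(c(d$recA, d$recB) %in% object@receptors))
      msg <- c(msg, "dimer references a receptor absent from the spec")
    key <- apply(cbind(pmin(d$recA, d$recB), pmax(d$recA, d$recB)), 1,
                 paste, collapse = ":")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate dimer under pair symmetry")
    e3 <- d$recA == "ErbB3" & d$recB == "ErbB3"
    if (object@variant %in% c("full", "with_igf1r_heterodimers") &&
        any(e3) && any(d$signaling[e3]))
      msg <- c(msg, "ErbB3 homodimer must be non-signaling in this variant")
    if (object@variant == "full" && nrow(d) != 10L)
      msg <- c(msg, "full variant must have exactly 10 dimers")
    if (object@variant == "no_heterodimers" &&
        (nrow(d) != 5L || !all(d$recA == d$recB) || !all(d$signaling)))
      msg <- c(msg, paste("no_heterodimers variant must contain the 5",
                          "homodimers, all signaling"))
  }
  if (!all(object@ligands$receptor %in% object@receptors))
    msg <- c(msg, "ligand maps to a receptor absent from the spec")
  if (length(msg)) msg else TRUE
})

#' Compiled signaling model
#'
#' An evaluable model: the network spec, the shared kinetic parameter set,
#' and the index structures (state inventory, monomer-pair list for dimer
#' formation, dimer/trafficking indices) consumed by the compiled
#' right-hand side.
#'
#' @slot spec the [RTKModelSpec-class] the model was built from.
#' @slot params named numeric vector of shared kinetic parameters.
#' @slot structure internal index structures (list).
#' @slot stateNames character vector naming the state inventory.
#' @exportClass RTKModel
setClass("RTKModel",
  representation(
    spec = "RTKModelSpec",
    params = "numeric",
    structure = "list",
    stateNames = "character"
  )
)

#' Panel of cell-line contexts
#'
#' Receptor surface expression (molecules/cell) plus KRAS/PIK3CA mutation
#' flags for a set of cell lines.  Mutation flags are inputs to the
#' classifier only; they do not alter the ODE structure.
#'
#' @slot data data.frame with columns `cell_line`, `kras_mutant`,
#'   `pik3ca_mutant` and one numeric column per receptor.
#' @exportClass CellLinePanel
setClass("CellLinePanel", representation(data = "data.frame"))

setValidity("CellLinePanel", function(object) {
  df <- object@data
  need <- c("cell_line", "kras_mutant", "pik3ca_mutant",
            "EGFR", "HER2", "ErbB3", "Met", "IGF1R")
  if (!all(need %in% names(df)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  rec <- as.matrix(df[, c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")])
  if (any(!is.finite(rec)) || any(rec < 0))
    return("receptor counts must be finite and >= 0")
  if (anyDuplicated(df$cell_line))
    return("duplicated cell line names")
  TRUE
})

#' Simulated trajectory
#'
#' Time-indexed model states and derived phospho-observables (per-dimer
#' phospho-level with surface and internal pools summed, plus pMEK, pERK,
#' pAKT, pS6K1 and pS6) for one cell line under one stimulus condition.
#'
#' @slot time numeric time grid (min).
#' @slot states matrix, time points x states.
#' @slot observables matrix, time points x observables.
#' @slot cellLine character scalar.
#' @slot doses named numeric vector of ligand doses (nM).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    time = "numeric",
    states = "matrix",
    observables = "matrix",
    cellLine = "character",
    doses = "numeric"
  )
)

#' Observation map
#'
#' Per-observable scale and offset parameters, noise level and
#' log-transform flag linking model states to measured concentrations.
#'
#' @slot map data.frame with columns `observable`, `scale`, `offset`,
#'   `sigma`, `log`.
#' @exportClass ObservationMap
setClass("ObservationMap", representation(map = "data.frame"))

setValidity("ObservationMap", function(object) {
  m <- object@map
  if (!all(c("observable", "scale", "offset", "sigma", "log") %in% names(m)))
    return("map must have columns observable, scale, offset, sigma, log")
  if (any(m$scale <= 0)) return("scale must be > 0")
  if (any(m$sigma <= 0)) return("sigma must be > 0")
  TRUE
})

#' Set of time-course measurements
#'
#' Tidy records of phospho-signaling measurements with their stimulus
#' condition and noise level.
#'
#' @slot data data.frame with columns `cell_line`, `observable`,
#'   `condition`, `time_min`, `replicate`, `value`, `sigma`.
#' @slot conditions named list mapping condition labels to named ligand
#'   dose vectors (nM).
#' @exportClass MeasurementSet
setClass("MeasurementSet",
  representation(data = "data.frame", conditions = "list"))

setValidity("MeasurementSet", function(object) {
  df <- object@data
  need <- c("cell_line", "observable", "condition", "time_min",
            "replicate", "value", "sigma")
  if (!all(need %in% names(df)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) && any(df$sigma <= 0)) return("sigma must be > 0")
  if (nrow(df) && !all(df$condition %in% names(object@conditions)))
    return("condition label without a dose entry")
  TRUE
})

#' Result of a maximum-likelihood fit
#'
#' @slot theta named numeric vector of optimized free parameters (log10).
#' @slot params full kinetic parameter vector after the fit.
#' @slot contexts [CellLinePanel-class] after the fit (receptor expression
#'   updated for co-fitted lines).
#' @slot chisq chi-square at the optimum.
#' @slot nPoints number of data points.
#' @slot nFree number of free parameters.
#' @slot starts data.frame of per-start diagnostics.
#' @slot seed integer seed used for the multi-start draw.
#' @slot trainLines cell lines present in the training data.
#' @exportClass FitResult
setClass("FitResult",
  representation(
    theta = "numeric",
    params = "numeric",
    contexts = "CellLinePanel",
    chisq = "numeric",
    nPoints = "integer",
    nFree = "integer",
    starts = "data.frame",
    seed = "integer",
    trainLines = "character"
  )
)

#' Ensemble of bagged decision trees
#'
#' @slot trees list of flat split-record tables (one per tree).
#' @slot featureNames character vector; order of the feature columns.
#' @slot importance named numeric; mean split gain per feature over all
#'   trees (unnormalized).
#' @slot nTrees integer.
#' @slot criterion `"snr"` or `"gini"`.
#' @slot seed integer.
#' @slot params list of training hyperparameters (depth limit, min leaf,
#'   bootstrap fraction, log10 transform settings).
#' @exportClass BaggedTreeModel
setClass("BaggedTreeModel",
  representation(
    trees = "list",
    featureNames = "character",
    importance = "numeric",
    nTrees = "integer",
    criterion = "character",
    seed = "integer",
    params = "list"
  )
)

#' Split-evaluation of prediction accuracy
#'
#' Per-repetition held-out accuracy under repeated random splits of the
#' cell lines into training and testing sets.
#'
#' @slot accuracies numeric vector, one fraction of true predictions per
#'   repetition.
#' @slot targetLigand ligand whose rows were scored (or `"combined"`).
#' @slot nReps integer repetition count.
#' @slot trainFraction fraction of cell lines used for training.
#' @slot seed integer.
#' @slot control logical; TRUE if labels were assigned at random (the
#'   50\%-accuracy control).
#' @exportClass SplitEvaluation
setClass("SplitEvaluation",
  representation(
    accuracies = "numeric",
    targetLigand = "character",
    nReps = "integer",
    trainFraction = "numeric",
    seed = "integer",
    control = "logical"
  )
)

setValidity("SplitEvaluation", function(object) {
  a <- object@accuracies
  if (any(a < 0 | a > 1)) return("accuracies must lie in [0, 1]")
  TRUE
})

#' Linear map between receptor mRNA and surface counts
#'
#' Per-receptor least-squares fit on the log10-log10 scale.
#'
#' @slot coefs data.frame with columns `receptor`, `intercept`, `slope`,
#'   `r_squared`, `n`.
#' @exportClass LinearMap
setClass("LinearMap", representation(coefs = "data.frame"))
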