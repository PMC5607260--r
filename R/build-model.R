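# Assembles the state inventory and index structures consumed by the
# compiled right-hand side.
#
# State inventory (per the smallest set supporting every arrow of the
# network): free surface monomer per receptor; ligand-bound surface
# monomer per (ligand, receptor) pair; per dimer a phosphorylated surface
# pool and an internalized pool (the non-signaling ErbB3 homodimer uses
# the same two pools but stays unphosphorylated and carries zero pathway
# weight); active fractions of MEK, ERK, AKT, S6K1 and S6 with conserved
# totals.  Ligand is a constant bath input, not a state.

buildStructure <- function(spec) {
  rec <- spec@receptors
  nR <- length(rec)
  stateNames <- rec
  # ligand-bound monomers
  bound <- spec@ligands
  bound$state <- paste0(bound$receptor, ".", bound$ligand)
  bound$recIdx <- match(bound$receptor, rec) - 1L
  bound$idx <- nR + seq_len(nrow(bound)) - 1L
  stateNames <- c(stateNames, bound$state)
  # dimers: surface (phospho) and internal pools
  d <- spec@dimers
  d$name <- dimerName(d$recA, d$recB)
  d$homo <- d$recA == d$recB
  d$recAi <- match(d$recA, rec) - 1L
  d$recBi <- match(d$recB, rec) - 1L
  base <- length(stateNames)
  d$iDs <- base + 2L * (seq_len(nrow(d)) - 1L)
  d$iDi <- d$iDs + 1L
  pre <- ifelse(d$signaling, "pD.", "D.")
  dsNames <- paste0(pre, d$recA, ".", d$recB, ".s")
  diNames <- paste0(pre, d$recA, ".", d$recB, ".i")
  nm <- character(2L * nrow(d))
  nm[seq(1, length(nm), 2)] <- dsNames
  nm[seq(2, length(nm), 2)] <- diNames
  stateNames <- c(stateNames, nm)
  # downstream active fractions
  down <- c("pMEK", "pERK", "pAKT", "pS6K1", "pS6")
  downIdx <- length(stateNames) + seq_along(down) - 1L
  stateNames <- c(stateNames, down)

  # monomer pools per receptor: free + each bound form
  pools <- lapply(seq_len(nR), function(r) {
    b <- bound[bound$recIdx == r - 1L, , drop = FALSE]
    data.frame(idx = c(r - 1L, b$idx),
               ligand = c(NA_character_, b$ligand),
               stringsAsFactors = FALSE)
  })
  # dimer-formation pair list
  prs <- list()
  for (k in seq_len(nrow(d))) {
    pa <- pools[[d$recAi[k] + 1L]]
    pb <- pools[[d$recBi[k] + 1L]]
    if (d$homo[k]) {
      m <- nrow(pa)
      for (u in seq_len(m)) for (v in u:m) {
        prs[[length(prs) + 1L]] <- list(
          i = pa$idx[u], j = pa$idx[v], d = k - 1L, same = (u == v),
          ligs = c(pa$ligand[u], pa$ligand[v]))
      }
    } else {
      for (u in seq_len(nrow(pa))) for (v in seq_len(nrow(pb))) {
        prs[[length(prs) + 1L]] <- list(
          i = pa$idx[u], j = pb$idx[v], d = k - 1L, same = FALSE,
          ligs = c(pa$ligand[u], pb$ligand[v]))
      }
    }
  }
  pairs <- data.frame(
    i = vapply(prs, `[[`, 0L, "i"),
    j = vapply(prs, `[[`, 0L, "j"),
    d = vapply(prs, `[[`, 0L, "d"),
    same = vapply(prs, function(p) as.integer(p$same), 0L))
  pairs$bothFree <- vapply(prs, function(p) all(is.na(p$ligs)), TRUE)
  pairs$het <- !d$homo[pairs$d + 1L]
  pairs$kascName <- paste0("kasc_", d$name[pairs$d + 1L])
  # per-ligand dimerization multiplier exponents (e.g. BTC-bound EGFR)
  multNames <- paste0("mult_", rep(spec@ligands$ligand, each = nrow(d)),
                      "_", rep(d$name, nrow(spec@ligands)))
  multCount <- vapply(multNames, function(mn) {
    parts <- strsplit(sub("^mult_", "", mn), "_", fixed = TRUE)[[1]]
    lig <- parts[1]; dnm <- parts[2]
    vapply(seq_along(prs), function(q) {
      if (d$name[prs[[q]]$d + 1L] != dnm) return(0L)
      sum(!is.na(prs[[q]]$ligs) & prs[[q]]$ligs == lig)
    }, 0L)
  }, integer(length(prs)))
  keep <- colSums(multCount) > 0
  multCount <- multCount[, keep, drop = FALSE]

  obsDim <- d[d$signaling, , drop = FALSE]
  obsNames <- c(paste0("pD_", obsDim$recA, "_", obsDim$recB),
                paste0("p", rec), down)

  list(nState = length(stateNames), stateNames = stateNames,
       nR = nR, receptors = rec, iR = 0:(nR - 1L),
       bound = bound, dimers = d, pairs = pairs, multCount = multCount,
       downIdx = downIdx, downNames = down, obsNames = obsNames,
       obsDimerRows = which(d$signaling))
}

#' Build a compiled signaling model
#'
#' Validates the kinetic parameter set against the network spec and
#' assembles the evaluable right-hand side implementing receptor
#' synthesis/turnover, ligand binding, spontaneous and ligand-driven
#' dimerization (dimer formation yields the phosphorylated dimer except
#' for non-signaling dimers), internalization, recycling or lysosomal
#' degradation, and the MEK/ERK and AKT cascades converging on S6K1 and
#' S6, with negative feedback of pERK on the MAPK input and of pS6K1 on
#' the PI3K input.
#'
#' @param spec an [RTKModelSpec-class].
#' @param params named numeric kinetic parameter vector; see
#'   [defaultKinetics()].
#' @return an [RTKModel-class].
#' @examples
#' m <- buildModel(rtkModelSpec("full"), defaultKinetics())
#' nStates(m)
#' @export
buildModel <- function(spec = rtkModelSpec("full"),
                       params = defaultKinetics(spec)) {
  stopifnot(is(spec, "RTKModelSpec"))
  validObject(spec)
  validateKinetics(spec, params)
  st <- buildStructure(spec)
  new("RTKModel", spec = spec, params = params, structure = st,
      stateNames = st$stateNames)
}

modelWithParams <- function(model, params) {
  validateKinetics(model@spec, params)
  model@params <- params
  model
}

updateParams <- function(model, replace) {
  p <- model@params
  unknown <- setdiff(names(replace), names(p))
  if (length(unknown))
    ltStop("config", paste("unknown kinetic parameter(s):",
                           paste(unknown, collapse = ", ")))
  p[names(replace)] <- replace
  modelWithParams(model, p)
}

# pack the current parameter values + per-context synthesis rates and
# ligand doses into the flat structure the compiled RHS consumes
packParms <- function(model, syn, doses = numeric(0)) {
  st <- model@structure
  p <- model@params
  b <- st$bound
  u <- setNames(rep(0, nrow(b)), b$ligand)
  if (length(doses)) {
    bad <- setdiff(names(doses), b$ligand)
    if (length(bad))
      ltStop("config", paste("unknown ligand(s):",
                             paste(bad, collapse = ", ")))
    if (any(doses < 0)) ltStop("config", "ligand doses must be >= 0")
    u[names(doses)] <- doses
  }
  kon <- unname(p[paste0("kon_", b$ligand)])
  koff <- kon * unname(p[paste0("KD_", b$ligand)])
  pr <- st$pairs
  mult <- rep(1, nrow(pr))
  if (ncol(st$multCount)) {
    for (mn in colnames(st$multCount)) {
      mv <- if (mn %in% names(p)) p[[mn]] else 1
      mult <- mult * mv^st$multCount[, mn]
    }
  }
  pK <- unname(p[pr$kascName]) *
    ifelse(pr$bothFree, p[["f_spont"]], 1) *
    ifelse(pr$het, p[["het_scale"]], 1) * mult
  d <- st$dimers
  P <- list(
    nState = st$nState, nR = st$nR, nB = nrow(b), nPairs = nrow(pr),
    nD = nrow(d),
    iR = st$iR, bRec = b$recIdx, iB = b$idx,
    pI = pr$i, pJ = pr$j, pD = pr$d, pSame = pr$same,
    iDs = d$iDs, iDi = d$iDi, dRecA = d$recAi, dRecB = d$recBi,
    dHomo = as.integer(d$homo),
    iMEK = st$downIdx[1], iERK = st$downIdx[2], iAKT = st$downIdx[3],
    iS6K = st$downIdx[4], iS6 = st$downIdx[5],
    syn = as.numeric(syn), kdegR = rep(p[["kdeg_R"]], st$nR),
    konu = kon * unname(u), koff = koff,
    pK = pK,
    kd = unname(p[paste0("kdis_", d$name)]),
    ki = unname(p[paste0("kint_", d$name)]),
    kr = unname(p[paste0("krec_", d$name)]),
    kx = unname(p[paste0("kxdeg_", d$name)]),
    wM = unname(p[paste0("wMAPK_", d$name)]),
    wP = unname(p[paste0("wPI3K_", d$name)]),
    tot = unname(p[c("MEK_total", "ERK_total", "AKT_total",
                     "S6K1_total", "S6_total")]),
    ka = unname(p[c("ka_MEK", "ka_ERK", "ka_AKT", "ka_S6K1_ERK",
                    "ka_S6K1_AKT", "ka_S6")]),
    kdd = unname(p[c("kd_MEK", "kd_ERK", "kd_AKT", "kd_S6K1", "kd_S6")]),
    kfbE = p[["kfb_ERK"]], kfbS = p[["kfb_S6K1"]],
    gamma = p[["gamma_internal"]]
  )
  packModelCpp(P)
}

# derived phospho-observables from a state matrix (rows = time points)
observableMatrix <- function(model, S) {
  st <- model@structure
  d <- st$dimers
  rows <- st$obsDimerRows
  pools <- lapply(seq_len(nrow(d)), function(k)
    S[, d$iDs[k] + 1L, drop = TRUE] + S[, d$iDi[k] + 1L, drop = TRUE])
  out <- matrix(0, nrow = nrow(S), ncol = length(st$obsNames),
                dimnames = list(NULL, st$obsNames))
  for (q in seq_along(rows)) {
    k <- rows[q]
    out[, paste0("pD_", d$recA[k], "_", d$recB[k])] <- pools[[k]]
  }
  for (r in st$receptors) {
    acc <- 0
    for (k in rows) {
      mult <- (d$recA[k] == r) + (d$recB[k] == r)
      if (mult > 0) acc <- acc + mult * pools[[k]]
    }
    out[, paste0("p", r)] <- acc
  }
  for (q in seq_along(st$downNames))
    out[, st$downNames[q]] <- S[, st$downIdx[q] + 1L]
  out
}

#' @describeIn buildModel number of ODE states of the compiled model.
#' @param object an [RTKModel-class].
#' @export
setMethod("nStates", "RTKModel", function(object) {
  object@structure$nState
})

#' @rdname buildModel
#' @export
setMethod("stateNames", "RTKModel", function(object) object@stateNames)

#' @rdname buildModel
#' @export
setMethod("dimerNames", "RTKModel", function(object) {
  dimerNames(object@spec)
})

#' @rdname buildModel
#' @export
setMethod("modelVariant", "RTKModel", function(object) {
  object@spec@variant
})

#' @rdname buildModel
#' @export
setMethod("observableNames", "RTKModel", function(object) {
  object@structure$obsNames
})

#' @rdname buildModel
#' @export
setMethod("kineticParams", "RTKModel", function(object) object@params)

setMethod("show", "RTKModel", function(object) {
  cat("RTKModel (variant:", object@spec@variant, ")\n")
  cat("  states:     ", nStates(object), "\n")
  cat("  dimer pools:", nrow(object@spec@dimers), "\n")
  cat("  observables:", length(observableNames(object)), "\n")
  cat("  parameters: ", length(object@params), "\n")
})
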