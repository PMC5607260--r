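# Synthetic-data generators with known ground truth for every pipeline
# stage: cell-line panels, noisy phospho time courses, viability screens
# with a planted response rule, and expression cohorts.  All generators
# are bit-reproducible from their seed.

#' Generate a synthetic cell-line panel
#'
#' Receptor surface counts drawn log-uniform over 3e3 -- 5.5e6
#' molecules/cell (the span of the packaged panel) and KRAS/PIK3CA
#' mutation flags drawn with the packaged panel's mutant frequencies
#' (computed from the fixture at run time).
#'
#' @param n number of cell lines (>= 2).
#' @param seed integer seed.
#' @param fixture if TRUE, return the packaged 58-line panel instead.
#' @return a [CellLinePanel-class].
#' @export
makeCellLines <- function(n = 58, seed = 1, fixture = FALSE) {
  if (fixture) return(loadCellLinePanel())
  if (n < 2) ltStop("precondition", "n must be >= 2")
  ref <- loadCellLinePanel()@data
  pKras <- mean(ref$kras_mutant)
  pPik <- mean(ref$pik3ca_mutant)
  set.seed(as.integer(seed))
  lo <- log10(3e3); hi <- log10(5.5e6)
  rec <- matrix(10^runif(5 * n, lo, hi), nrow = n,
                dimnames = list(NULL, RECEPTORS))
  cellLinePanel(data.frame(
    cell_line = sprintf("SL%02d", seq_len(n)),
    kras_mutant = runif(n) < pKras,
    pik3ca_mutant = runif(n) < pPik,
    rec, stringsAsFactors = FALSE))
}

#' Default stimulus design for synthetic time courses
#'
#' Four doses per ligand spanning 0.156 -- 10 nM plus pairwise
#' co-stimulations at 2.5 nM of each ligand.
#'
#' @param ligands ligands in the design.
#' @param doses single-ligand dose series (nM).
#' @param coDose co-stimulation dose (nM); NULL disables co-stimulation.
#' @return named list mapping condition labels to dose vectors.
#' @export
defaultStimulusDesign <- function(ligands = c("EGF", "HRG", "IGF1"),
                                  doses = c(0.156, 0.625, 2.5, 10),
                                  coDose = 2.5) {
  out <- list()
  for (lg in ligands) for (d in doses)
    out[[paste0(lg, "@", d)]] <- setNames(d, lg)
  if (!is.null(coDose) && length(ligands) > 1) {
    prs <- combn(ligands, 2)
    for (k in seq_len(ncol(prs))) {
      lab <- paste0(prs[1, k], "+", prs[2, k], "@", coDose)
      out[[lab]] <- setNames(rep(coDose, 2), prs[, k])
    }
  }
  out
}

#' Simulate noisy phospho time courses
#'
#' Simulates the model for every (cell line, condition), applies the
#' observation map's scale/offset, and multiplies log-normal measurement
#' noise (for log-flagged observables; additive Gaussian otherwise).
#'
#' @param model the ground-truth [RTKModel-class].
#' @param panel a [CellLinePanel-class] (the ground-truth expression).
#' @param obsMap an [ObservationMap-class]; defaults to
#'   [defaultObservationMap()] with noise `sigma`.
#' @param stimuli named list of dose vectors; defaults to
#'   [defaultStimulusDesign()].
#' @param times measurement time grid.
#' @param sigma log-scale noise standard deviation of the default map.
#' @param noise if FALSE, record the exact model observations (the
#'   sigma column keeps the map's positive noise level).
#' @param seed integer seed.
#' @return a [MeasurementSet-class].
#' @export
makeTimecourses <- function(model, panel, obsMap = NULL,
                            stimuli = defaultStimulusDesign(),
                            times = defaultTimeGrid(), sigma = 0.15,
                            noise = TRUE, seed = 1) {
  obsMap <- obsMap %||% defaultObservationMap(model, sigma = sigma)
  m <- obsMap@map
  set.seed(as.integer(seed))
  rows <- list()
  for (line in cellLines(panel)) {
    ctx <- cellContext(panel, line)
    ss <- steadyState(model, ctx)
    for (cond in names(stimuli)) {
      traj <- simulateTrajectory(model, ctx, doses = stimuli[[cond]],
                                 times = times, ss = ss)
      for (k in seq_len(nrow(m))) {
        x <- traj@observables[, m$observable[k]]
        g <- m$scale[k] * x + m$offset[k]
        val <- if (!noise) g
        else if (m$log[k]) {
          pmax(g, 1e-12) * exp(rnorm(length(g), 0, m$sigma[k]))
        } else {
          g + rnorm(length(g), 0, m$sigma[k])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = line, observable = m$observable[k],
          condition = cond, time_min = times, replicate = 1L,
          value = val, sigma = m$sigma[k], stringsAsFactors = FALSE)
      }
    }
  }
  measurementSet(do.call(rbind, rows), stimuli)
}

#' Plant a phenotype rule on simulated features
#'
#' The default planted rule labels a (cell line, ligand) pair as
#' responder iff its pS6 AUC exceeds the panel median -- a depth-1 rule
#' on the true features, well within the depth-3 budget a shallow tree
#' can express.
#'
#' @param features feature table from [featureTable()].
#' @param rule `"ps6_median"` or `"ps6_or_akt"` (responder iff pS6 AUC
#'   above its median OR pAKT AUC above its upper quartile, a depth-2
#'   rule).
#' @return data.frame with `cell_line`, `ligand`, `responder`.
#' @export
plantPhenotype <- function(features, rule = c("ps6_median",
                                              "ps6_or_akt")) {
  rule <- match.arg(rule)
  s6 <- features$auc_pS6
  lab <- switch(rule,
    ps6_median = s6 > median(s6),
    ps6_or_akt = s6 > median(s6) |
      features$auc_pAKT > quantile(features$auc_pAKT, 0.75))
  data.frame(cell_line = features$cell_line, ligand = features$ligand,
             responder = lab, stringsAsFactors = FALSE)
}

#' Generate a synthetic viability screen
#'
#' Quadruplicate day-0/day-3 luminescence per (cell line, treatment):
#' the day-3 mean of a planted responder is control x (1 + effect),
#' non-responders sit at the control level, replicates carry a 5\%
#' coefficient of variation, and a stated fraction of labels is flipped
#' (label noise).
#'
#' @param labels planted labels from [plantPhenotype()].
#' @param effect proliferative effect of a responder (0.3 = 30\% above
#'   control).
#' @param cv replicate coefficient of variation.
#' @param labelNoise fraction of labels flipped before generation.
#' @param day0Mean baseline luminescence.
#' @param controlGrowth 3-day growth factor of the medium control.
#' @param nRep replicates per condition (quadruplicates).
#' @param seed integer seed.
#' @return viability data.frame (`cell_line`, `treatment`, `day`,
#'   `replicate`, `value`) with the medium control included; attribute
#'   `planted` carries the post-noise effective labels.
#' @export
makeViability <- function(labels, effect = 0.3, cv = 0.05,
                          labelNoise = 0.10, day0Mean = 1000,
                          controlGrowth = 3, nRep = 4, seed = 1) {
  set.seed(as.integer(seed))
  eff <- labels
  if (labelNoise > 0) {
    flip <- runif(nrow(eff)) < labelNoise
    eff$responder <- xor(eff$responder, flip)
  }
  noise <- function(mu, n) {
    if (cv <= 0) rep(mu, n)
    else mu * exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
  }
  rows <- list()
  add <- function(line, tr, day, vals)
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_line = line, treatment = tr, day = day,
      replicate = seq_along(vals), value = vals,
      stringsAsFactors = FALSE)
  ctrlDay3 <- day0Mean * controlGrowth
  for (line in unique(eff$cell_line)) {
    add(line, "medium", 0, noise(day0Mean, nRep))
    add(line, "medium", 3, noise(ctrlDay3, nRep))
    sub <- eff[eff$cell_line == line, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      mu3 <- ctrlDay3 * (1 + effect * sub$responder[k])
      add(line, sub$ligand[k], 0, noise(day0Mean, nRep))
      add(line, sub$ligand[k], 3, noise(mu3, nRep))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "planted") <- eff
  out
}

#' Generate a synthetic expression cohort
#'
#' Per-gene log-normal TPM for the five receptor genes and the four
#' ligand genes.  Planted responders are the samples whose simulated pS6
#' AUC (after the cohort mean-normalization the prediction pipeline
#' applies) falls above the (1 - responderFraction) quantile, and their
#' target-ligand gene is shifted up by `ligandShift` log2 units.
#'
#' @param model ground-truth [RTKModel-class].
#' @param nSamples cohort size.
#' @param responderFraction planted responder fraction in [0, 1].
#' @param ligand target ligand.
#' @param ligandShift log2 shift of the ligand gene in responders.
#' @param panelRef reference panel anchoring the normalization.
#' @param doses screen doses (nM).
#' @param sdlog log-normal spread of receptor TPM.
#' @param seed integer seed.
#' @return list with `expr` (samples x genes TPM matrix), `planted`
#'   (logical), `ligandGene`, `features` (the simulated feature table).
#' @export
makeCohort <- function(model, nSamples = 400, responderFraction = 0.5,
                       ligand = "HRG", ligandShift = 1,
                       panelRef = loadCellLinePanel(),
                       doses = c(EGF = 5, HRG = 5, HGF = 1, IGF1 = 50),
                       sdlog = 1, seed = 1) {
  if (responderFraction < 0 || responderFraction > 1)
    ltStop("precondition", "responderFraction must lie in [0, 1]")
  set.seed(as.integer(seed))
  recGenes <- names(GENE_TO_RECEPTOR)
  recMean <- c(EGFR = 50, ERBB2 = 30, ERBB3 = 20, MET = 30, IGF1R = 20)
  ligGenes <- unname(LIGAND_TO_GENE)
  expr <- cbind(
    vapply(recGenes, function(g)
      exp(rnorm(nSamples, log(recMean[[g]]), sdlog)),
      numeric(nSamples)),
    vapply(ligGenes, function(g)
      exp(rnorm(nSamples, log(10), 0.7)), numeric(nSamples)))
  rownames(expr) <- sprintf("S%04d", seq_len(nSamples))
  counts <- cohortSurfaceCounts(expr, panelRef)
  panel <- cellLinePanel(data.frame(
    cell_line = rownames(expr), kras_mutant = FALSE,
    pik3ca_mutant = FALSE, counts, stringsAsFactors = FALSE))
  ft <- featureTable(model, panel, ligands = ligand, doses = doses)
  s6 <- ft$auc_pS6
  planted <- if (responderFraction >= 1) rep(TRUE, nSamples)
    else s6 > quantile(s6, 1 - responderFraction)
  gene <- LIGAND_TO_GENE[[ligand]]
  expr[planted, gene] <- expr[planted, gene] * 2^ligandShift
  list(expr = expr, planted = planted, ligandGene = gene,
       features = ft)
}
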