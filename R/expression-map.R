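# Receptor mRNA <-> surface-count mapping and cohort-scale prediction of
# ligand-dependent samples.

GENE_TO_RECEPTOR <- c(EGFR = "EGFR", ERBB2 = "HER2", ERBB3 = "ErbB3",
                      MET = "Met", IGF1R = "IGF1R")
LIGAND_TO_GENE <- c(EGF = "EGF", HRG = "NRG1", HGF = "HGF",
                    IGF1 = "IGF1")

#' Fit the mRNA-to-surface-count linear map
#'
#' Per-receptor least squares on the log10-log10 scale between mRNA
#' expression (TPM) and absolute surface counts (qFACS scale).
#'
#' @param pairs data.frame with columns `receptor`, `mrna`, `surface`
#'   (>= 3 positive pairs per receptor; non-positive values are filtered
#'   with a message).
#' @return a [LinearMap-class].
#' @export
fitLinearMap <- function(pairs) {
  stopifnot(all(c("receptor", "mrna", "surface") %in% names(pairs)))
  out <- list()
  for (r in unique(pairs$receptor)) {
    sub <- pairs[pairs$receptor == r, , drop = FALSE]
    keep <- sub$mrna > 0 & sub$surface > 0
    if (any(!keep))
      message(sum(!keep), " non-positive pair(s) filtered for ", r)
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 3)
      ltStop("precondition", paste0(
        "need >= 3 positive (mRNA, surface) pairs for ", r))
    fit <- lm(log10(surface) ~ log10(mrna), data = sub)
    out[[r]] <- data.frame(
      receptor = r, intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      r_squared = summary(fit)$r.squared, n = nrow(sub),
      stringsAsFactors = FALSE)
  }
  new("LinearMap", coefs = do.call(rbind, out))
}

#' Predict surface counts from mRNA via a linear map
#'
#' @param map a [LinearMap-class].
#' @param receptor receptor name.
#' @param mrna TPM values.
#' @return surface counts (molecules/cell).
#' @export
predictSurface <- function(map, receptor, mrna) {
  cf <- map@coefs[map@coefs$receptor == receptor, , drop = FALSE]
  if (nrow(cf) != 1L)
    ltStop("schema", paste0("no linear map for receptor '", receptor,
                            "'"))
  10^(cf$intercept + cf$slope * log10(pmax(mrna, 1e-12)))
}

setMethod("show", "LinearMap", function(object) {
  cat("LinearMap (log10 surface ~ log10 mRNA)\n")
  print(object@coefs, row.names = FALSE)
})

# per-sample receptor surface counts from a cohort expression matrix:
# per-gene mean-normalization anchored to the reference panel's mean
# surface counts (the in vitro and cohort scales differ, so expressions
# are normalized to their respective means)
cohortSurfaceCounts <- function(expr, panelRef, map = NULL) {
  need <- names(GENE_TO_RECEPTOR)
  miss <- setdiff(need, colnames(expr))
  if (length(miss))
    ltStop("schema", paste("missing gene column(s):",
                           paste(miss, collapse = ", ")))
  counts <- matrix(NA_real_, nrow(expr), length(need),
                   dimnames = list(rownames(expr),
                                   unname(GENE_TO_RECEPTOR)))
  refMeans <- colMeans(panelRef@data[, RECEPTORS])
  for (g in need) {
    r <- GENE_TO_RECEPTOR[[g]]
    tpm <- expr[, g]
    if (!is.null(map)) {
      counts[, r] <- predictSurface(map, r, tpm)
    } else {
      mu <- mean(tpm)
      norm <- if (mu > 0) tpm / mu else rep(0, length(tpm))
      counts[, r] <- norm * refMeans[[r]]
    }
  }
  counts
}

#' Predict ligand-dependent samples in an expression cohort
#'
#' Converts per-sample receptor mRNA to model-scale surface counts (by
#' per-gene mean normalization anchored to the reference panel, or via a
#' fitted [LinearMap-class]), simulates the signaling features for the
#' chosen ligand, and votes with a trained bagged-tree ensemble.
#' Mutation flags are taken as wild type when the cohort provides none.
#'
#' @param expr samples x genes TPM matrix (see
#'   [readExpressionTable()]).
#' @param model an [RTKModel-class].
#' @param bdt a [BaggedTreeModel-class] trained on feature tables of the
#'   same model.
#' @param ligand ligand to test (`"EGF"`, `"HRG"`, `"HGF"`, `"IGF1"`).
#' @param panelRef reference [CellLinePanel-class] anchoring the
#'   normalization (default: the packaged panel).
#' @param map optional [LinearMap-class] replacing mean normalization.
#' @param doses screen doses (nM).
#' @param indication optional per-sample indication labels for the
#'   per-indication responder fractions.
#' @return data.frame with `sample`, `responder`, `vote`; attribute
#'   `responderFraction` (and `byIndication` if given).
#' @export
cohortPredict <- function(expr, model, bdt, ligand,
                          panelRef = loadCellLinePanel(), map = NULL,
                          doses = c(EGF = 5, HRG = 5, HGF = 1,
                                    IGF1 = 50),
                          indication = NULL) {
  if (nrow(expr) == 0)
    return(data.frame(sample = character(0), responder = logical(0),
                      vote = numeric(0)))
  counts <- cohortSurfaceCounts(expr, panelRef, map)
  panel <- cellLinePanel(data.frame(
    cell_line = rownames(expr) %||% paste0("S", seq_len(nrow(expr))),
    kras_mutant = FALSE, pik3ca_mutant = FALSE,
    counts, stringsAsFactors = FALSE))
  ft <- featureTable(model, panel, ligands = ligand, doses = doses)
  vote <- predict(bdt, ft, type = "vote")
  resp <- predict(bdt, ft, type = "class")
  out <- data.frame(sample = ft$cell_line, responder = resp,
                    vote = vote, stringsAsFactors = FALSE)
  attr(out, "responderFraction") <- mean(resp)
  if (!is.null(indication)) {
    idx <- match(out$sample, rownames(expr))
    byInd <- tapply(out$responder, indication[idx], mean)
    attr(out, "byIndication") <- byInd
  }
  out
}

#' Ligand-expression association of predicted responders
#'
#' Two-sample t-test of the log2 ligand gene expression between
#' predicted responders and non-responders.
#'
#' @param expr samples x genes TPM matrix.
#' @param predictions logical vector (TRUE = predicted responder),
#'   aligned with the rows of `expr`.
#' @param ligandGene ligand gene column (e.g. `"NRG1"`).
#' @return list with `meanDiff` (log2), `statistic`, `p.value`, `n`.
#' @export
ligandAssociation <- function(expr, predictions, ligandGene) {
  if (!ligandGene %in% colnames(expr))
    ltStop("schema", paste("missing gene column:", ligandGene))
  if (length(predictions) != nrow(expr))
    ltStop("pairing", "predictions and expression rows differ")
  if (all(predictions) || all(!predictions))
    ltStop("validity",
           "both predicted classes must be non-empty for the t-test")
  x <- log2(pmax(expr[predictions, ligandGene], 1e-9))
  y <- log2(pmax(expr[!predictions, ligandGene], 1e-9))
  tt <- t.test(x, y)
  list(meanDiff = unname(mean(x) - mean(y)),
       statistic = unname(tt$statistic), p.value = tt$p.value,
       n = c(responders = length(x), nonResponders = length(y)))
}
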