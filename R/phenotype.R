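# Responder calling from the 3-day viability screen: effect ratio versus
# the respective control plus a two-sided Wilcoxon rank-sum test on the
# replicate vectors (exact enumeration at quadruplicate scale).

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For combined sample sizes up to 12 (the default for quadruplicates)
#' the two-sided p-value is computed by exact enumeration of all
#' choose(n, n_a) group assignments of the (mid-)ranks; ties are handled
#' by mid-ranks and reported.  Larger samples fall back to the normal
#' approximation of [stats::wilcox.test].  With quadruplicates the
#' smallest attainable p is 2/70 (complete separation); with triplicates
#' it is 2/20 = 0.1, which can never reach a 0.05 threshold.
#'
#' @param a,b numeric replicate vectors (length >= 2 each).
#' @param exact logical; defaults to TRUE when length(a)+length(b) <= 12.
#' @return an object of class `"htest"` with `statistic` (rank sum of
#'   `a`), `p.value` and a `ties` flag.
#' @examples
#' wilcoxonRankSum(c(5, 6, 7, 8), c(1, 2, 3, 4))$p.value  # 2/70
#' @export
wilcoxonRankSum <- function(a, b, exact = NULL) {
  if (length(a) < 2 || length(b) < 2)
    ltStop("precondition", "each replicate vector needs length >= 2")
  n <- length(a) + length(b)
  exact <- exact %||% (n <= 12)
  if (!exact) {
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))
    return(structure(list(statistic = c(W = unname(wt$statistic)),
                          p.value = wt$p.value, ties = anyDuplicated(
                            c(a, b)) > 0,
                          method = "Wilcoxon rank-sum (normal approx.)",
                          data.name = "a vs b"),
                     class = "htest"))
  }
  rk <- rank(c(a, b))  # mid-ranks under ties
  ties <- anyDuplicated(c(a, b)) > 0
  if (ties)
    message("ties present; exact enumeration uses mid-ranks")
  na <- length(a)
  Wobs <- sum(rk[seq_len(na)])
  mu <- na * (n + 1) / 2
  sets <- combn(n, na)
  Wall <- colSums(matrix(rk[sets], nrow = na))
  p <- mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-9)
  structure(list(statistic = c(W = Wobs), p.value = p, ties = ties,
                 method = "Exact Wilcoxon rank-sum (enumeration)",
                 data.name = "a vs b"),
            class = "htest")
}

#' Call a ligand (or antibody) response for one cell line
#'
#' A treatment is a responder if its day-3 signal exceeds the reference
#' by more than the threshold (default 20\%) AND the replicate difference
#' is significant at level alpha (default 0.05, exact two-sided Wilcoxon
#' rank-sum).  For inhibition calls (`direction = "decrease"`) the
#' mirrored rule applies (>= 20\% below, p < alpha).
#'
#' @param record list with elements `cell_line`, `treatment`, `day0`,
#'   `day3` (replicate vectors, values > 0).
#' @param reference list of the same shape: the medium control for ligand
#'   effects, or ligand alone for antibody-plus-ligand effects.
#' @param threshold effect-ratio threshold (1.20 = 20\% above control).
#' @param alpha significance level.
#' @param direction `"increase"` (proliferation) or `"decrease"`
#'   (inhibition).
#' @param ratioStat `"mean"` (default) or `"median"` for the effect
#'   ratio.
#' @return data.frame row with `cell_line`, `treatment`, `ratio`,
#'   `p_value`, `responder`, `log10_fc_day0`.
#' @export
callResponder <- function(record, reference, threshold = 1.20,
                          alpha = 0.05,
                          direction = c("increase", "decrease"),
                          ratioStat = c("mean", "median")) {
  direction <- match.arg(direction)
  ratioStat <- match.arg(ratioStat)
  if (!identical(record$cell_line, reference$cell_line))
    ltStop("pairing", sprintf(
      "record (%s) and reference (%s) are different cell lines",
      record$cell_line, reference$cell_line))
  stat <- if (ratioStat == "mean") mean else median
  for (v in list(record$day3, reference$day3)) {
    if (length(v) < 2 || any(v <= 0))
      ltStop("precondition",
             "day-3 replicates must be positive, length >= 2")
  }
  ratio <- stat(record$day3) / stat(reference$day3)
  p <- wilcoxonRankSum(record$day3, reference$day3)$p.value
  hit <- if (direction == "increase") ratio > threshold
         else ratio < 1 / threshold
  responder <- hit && p < alpha
  lfc <- if (!is.null(record$day0) && length(record$day0) >= 1)
    log10(stat(record$day3) / stat(record$day0)) else NA_real_
  data.frame(cell_line = record$cell_line,
             treatment = record$treatment, ratio = ratio, p_value = p,
             responder = responder, log10_fc_day0 = lfc,
             stringsAsFactors = FALSE)
}

viabilityRecord <- function(viab, line, treatment) {
  sub <- viab[viab$cell_line == line & viab$treatment == treatment, ,
              drop = FALSE]
  list(cell_line = line, treatment = treatment,
       day0 = sub$value[sub$day == 0], day3 = sub$value[sub$day == 3])
}

#' Call responders across a viability table
#'
#' @param viab data.frame with columns `cell_line`, `treatment`, `day`,
#'   `replicate`, `value` (see [readViabilityTable()]).
#' @param control treatment label of the reference (default
#'   `"medium"`).
#' @param threshold,alpha,direction,ratioStat see [callResponder()].
#' @return data.frame of calls, one row per (cell line, non-control
#'   treatment).
#' @export
callResponders <- function(viab, control = "medium", threshold = 1.20,
                           alpha = 0.05, direction = "increase",
                           ratioStat = "mean") {
  out <- list()
  for (line in unique(viab$cell_line)) {
    ref <- viabilityRecord(viab, line, control)
    if (length(ref$day3) < 2)
      ltStop("schema", paste("no control replicates for", line))
    for (tr in setdiff(unique(viab$treatment[viab$cell_line == line]),
                       control)) {
      rec <- viabilityRecord(viab, line, tr)
      out[[length(out) + 1L]] <-
        callResponder(rec, ref, threshold, alpha, direction, ratioStat)
    }
  }
  do.call(rbind, out)
}

#' Robustness sweep over the responder threshold
#'
#' Recomputes responder calls across a grid of effect-ratio thresholds
#' (10--30\% by default), to examine how label assignment depends on the
#' proliferation threshold.
#'
#' @param viab viability table (see [callResponders()]).
#' @param thresholds numeric vector of ratio thresholds.
#' @param ... passed to [callResponders()].
#' @return data.frame with one block of calls per threshold, stacked,
#'   with a `threshold` column.
#' @export
thresholdSweep <- function(viab, thresholds = 1 + seq(0.10, 0.30, 0.05),
                           ...) {
  do.call(rbind, lapply(thresholds, function(th) {
    calls <- callResponders(viab, threshold = th, ...)
    calls$threshold <- th
    calls
  }))
}
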