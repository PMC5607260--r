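RECEPTORS <- c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")

LIGAND_MAP <- data.frame(
  ligand   = c("EGF", "HRG", "HGF", "IGF1", "BTC"),
  receptor = c("EGFR", "ErbB3", "Met", "IGF1R", "EGFR"),
  stringsAsFactors = FALSE
)

dimerFrame <- function(recA, recB, signaling) {
  data.frame(recA = recA, recB = recB, signaling = signaling,
             stringsAsFactors = FALSE)
}

#' Construct a model network specification
#'
#' The production network (`"full"`) couples the five receptors through ten
#' homo- and heterodimers: the five homodimers plus EGFR:HER2, EGFR:ErbB3,
#' EGFR:Met, HER2:ErbB3 and ErbB3:Met.  The ErbB3 homodimer forms but
#' cannot trans-phosphorylate (no intrinsic kinase activity), so its
#' signaling mask is off.  `"with_igf1r_heterodimers"` additionally carries
#' EGFR:IGF1R and HER2:IGF1R (the two dimers whose removal leaves model
#' performance unchanged).  `"no_heterodimers"` is the reduced comparison
#' network: homodimers only, with every receptor allowed to signal through
#' its homodimer (including ErbB3).
#'
#' @param variant one of `"full"`, `"with_igf1r_heterodimers"`,
#'   `"no_heterodimers"`; `"no_igf1r_heterodimers"` is accepted as an alias
#'   of `"full"` (the network after IGF-1R heterodimer removal).
#' @return an [RTKModelSpec-class].
#' @examples
#' sp <- rtkModelSpec("full")
#' nrow(sp@dimers)  # 10
#' @export
rtkModelSpec <- function(variant = c("full", "no_igf1r_heterodimers",
                                     "with_igf1r_heterodimers",
                                     "no_heterodimers")) {
  variant <- match.arg(variant)
  if (variant == "no_igf1r_heterodimers") variant <- "full"
  homo <- dimerFrame(RECEPTORS, RECEPTORS,
                     signaling = RECEPTORS != "ErbB3")
  het <- dimerFrame(
    c("EGFR", "EGFR", "EGFR", "HER2", "ErbB3"),
    c("HER2", "ErbB3", "Met", "ErbB3", "Met"),
    signaling = TRUE)
  dimers <- switch(variant,
    full = rbind(homo, het),
    with_igf1r_heterodimers = rbind(
      homo, het, dimerFrame(c("EGFR", "HER2"), c("IGF1R", "IGF1R"), TRUE)),
    no_heterodimers = dimerFrame(RECEPTORS, RECEPTORS, signaling = TRUE)
  )
  feedback <- data.frame(
    source = c("pERK", "pS6K1"),
    target = c("MAPK_input", "PI3K_input"),
    sign = c(-1, -1),
    stringsAsFactors = FALSE)
  new("RTKModelSpec", variant = variant, receptors = RECEPTORS,
      ligands = LIGAND_MAP, dimers = dimers, feedbackLinks = feedback)
}

dimerName <- function(recA, recB) paste(recA, recB, sep = ":")

#' @describeIn rtkModelSpec dimer names of a spec.
#' @param object an [RTKModelSpec-class].
#' @export
setMethod("dimerNames", "RTKModelSpec", function(object) {
  dimerName(object@dimers$recA, object@dimers$recB)
})

#' @rdname rtkModelSpec
#' @export
setMethod("modelVariant", "RTKModelSpec", function(object) object@variant)

setMethod("show", "RTKModelSpec", function(object) {
  cat("RTKModelSpec (variant:", object@variant, ")\n")
  cat("  receptors:", paste(object@receptors, collapse = ", "), "\n")
  cat("  ligands:  ",
      paste(object@ligands$ligand, object@ligands$receptor,
            sep = "->", collapse = ", "), "\n")
  sig <- ifelse(object@dimers$signaling, "", "*")
  cat("  dimers:   ", paste0(dimerNames(object), sig, collapse = ", "),
      "\n")
  if (any(!object@dimers$signaling))
    cat("             (* = forms but cannot trans-phosphorylate)\n")
})
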