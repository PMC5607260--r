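#' Number of model states
#' @param object an object with a state inventory.
#' @return integer scalar.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' State names
#' @param object an object with a state inventory.
#' @return character vector.
#' @export
setGeneric("stateNames", function(object) standardGeneric("stateNames"))

#' Dimer names
#' @param object a model or model spec.
#' @return character vector like `"EGFR:HER2"`.
#' @export
setGeneric("dimerNames", function(object) standardGeneric("dimerNames"))

#' Model variant
#' @param object a model or model spec.
#' @return character scalar.
#' @export
setGeneric("modelVariant", function(object) standardGeneric("modelVariant"))

#' Observable names
#' @param object a model or trajectory.
#' @return character vector.
#' @export
setGeneric("observableNames",
           function(object) standardGeneric("observableNames"))

#' Cell line names
#' @param object a panel or fit result.
#' @return character vector.
#' @export
setGeneric("cellLines", function(object) standardGeneric("cellLines"))

#' Kinetic parameters
#' @param object a compiled model or fit result.
#' @return named numeric vector.
#' @export
setGeneric("kineticParams", function(object) standardGeneric("kineticParams"))

#' Per-repetition accuracies
#' @param object a [SplitEvaluation-class].
#' @return numeric vector.
#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))

#' Feature importance of a bagged-tree ensemble
#'
#' Mean split gain per feature over all trees of the ensemble.
#'
#' @param object a [BaggedTreeModel-class].
#' @param normalize logical; if TRUE (default) rescale so the largest
#'   importance is 1.
#' @return named numeric vector, one entry per feature.
#' @export
setGeneric("featureImportance",
           function(object, normalize = TRUE)
             standardGeneric("featureImportance"))
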