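# End-to-end orchestration: generate (or load) inputs, simulate the
# feature table, call responders, train and evaluate the bagged trees
# against the random control, and assemble a run report.  Every artifact
# written to disk carries the hash of the configuration that produced
# it.

#' Assemble a run configuration
#'
#' @param nLines panel size for synthetic runs (ignored with
#'   `fixturePanel`).
#' @param fixturePanel use the packaged 58-line panel.
#' @param variant model variant.
#' @param ligands screen ligands.
#' @param doses screen doses (nM).
#' @param responderThreshold effect-ratio threshold (1.20).
#' @param alpha significance level (0.05).
#' @param rule planted phenotype rule (see [plantPhenotype()]).
#' @param effect,cv,labelNoise viability generator settings.
#' @param nReps split repetitions (500).
#' @param trainFraction training fraction of cell lines.
#' @param nTrees,depthLimit,minLeaf,criterion ensemble hyperparameters.
#' @param seed master seed; stage seeds derive from it.
#' @param outDir optional output directory for CSV artifacts.
#' @return named list (the configuration).
#' @export
runConfig <- function(nLines = 58, fixturePanel = TRUE,
                      variant = "full",
                      ligands = c("EGF", "HRG", "HGF", "IGF1"),
                      doses = c(EGF = 5, HRG = 5, HGF = 1, IGF1 = 50),
                      responderThreshold = 1.20, alpha = 0.05,
                      rule = "ps6_median", effect = 0.3, cv = 0.05,
                      labelNoise = 0.10, nReps = 500,
                      trainFraction = 0.7, nTrees = 200,
                      depthLimit = 4, minLeaf = 3, criterion = "snr",
                      seed = 1, outDir = NULL) {
  as.list(environment())
}

#' Run the full synthetic pipeline
#'
#' synth/load -> features -> viability -> responder calls -> labeled set
#' -> split evaluation vs the random control -> report.  Deterministic
#' given the configuration (all stage seeds derive from `config$seed`).
#'
#' @param config list from [runConfig()].
#' @return list with elements `panel`, `features`, `calls`, `labeled`,
#'   `evaluation`, `control`, `comparisonP`, `importance`, `configHash`;
#'   element `failedStage` names the first failing stage, if any.
#' @export
runPipeline <- function(config = runConfig()) {
  hash <- configHash(config)
  report <- list(config = config, configHash = hash)
  stage <- function(name, fun) {
    if (!is.null(report$failedStage)) return(NULL)
    val <- try(fun(), silent = TRUE)
    if (inherits(val, "try-error")) {
      report$failedStage <<- name
      report$error <<- attr(val, "condition")$message
      NULL
    } else val
  }
  seed <- as.integer(config$seed)
  model <- stage("model", function()
    buildModel(rtkModelSpec(config$variant)))
  panel <- stage("panel", function() {
    if (config$fixturePanel) loadCellLinePanel()
    else makeCellLines(config$nLines, seed = seed)
  })
  features <- stage("features", function()
    featureTable(model, panel, ligands = config$ligands,
                 doses = config$doses))
  labels <- stage("plant", function()
    plantPhenotype(features, rule = config$rule))
  viab <- stage("viability", function()
    makeViability(labels, effect = config$effect, cv = config$cv,
                  labelNoise = config$labelNoise, seed = seed + 1L))
  calls <- stage("calls", function()
    callResponders(viab, threshold = config$responderThreshold,
                   alpha = config$alpha))
  labeled <- stage("label", function()
    labeledFeatureSet(features, calls))
  evaluation <- stage("evaluate", function()
    evaluateSplits(labeled, nReps = config$nReps,
                   trainFraction = config$trainFraction,
                   nTrees = config$nTrees,
                   depthLimit = config$depthLimit,
                   minLeaf = config$minLeaf,
                   criterion = config$criterion, seed = seed + 2L))
  control <- stage("control", function()
    evaluateSplits(labeled, nReps = config$nReps,
                   trainFraction = config$trainFraction,
                   nTrees = config$nTrees,
                   depthLimit = config$depthLimit,
                   minLeaf = config$minLeaf,
                   criterion = config$criterion, seed = seed + 3L,
                   control = TRUE))
  comparisonP <- stage("compare", function()
    compareToControl(evaluation, control))
  importance <- stage("importance", function() {
    ens <- trainBagged(labeled, nTrees = config$nTrees,
                       depthLimit = config$depthLimit,
                       minLeaf = config$minLeaf,
                       criterion = config$criterion, seed = seed + 4L)
    featureImportance(ens)
  })
  report$panel <- panel
  report$features <- features
  report$calls <- calls
  report$labeled <- labeled
  report$evaluation <- evaluation
  report$control <- control
  report$comparisonP <- comparisonP
  report$importance <- importance
  if (!is.null(config$outDir) && is.null(report$failedStage)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm)
      writeCsvWithHash(df, file.path(config$outDir, nm), hash)
    wr(features, "features.csv")
    wr(calls, "responder_calls.csv")
    wr(data.frame(rep = seq_along(accuracies(evaluation)),
                  accuracy = accuracies(evaluation),
                  control = accuracies(control)),
       "split_accuracies.csv")
    wr(data.frame(feature = names(importance),
                  importance = unname(importance)),
       "feature_importance.csv")
  }
  report
}
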