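# Bagged decision trees with a signal-to-noise split gain, the
# cell-line split-evaluation harness, and feature importance.

#' Join simulated features to responder labels
#'
#' @param features feature table from [featureTable()].
#' @param calls responder calls from [callResponders()] (treatments must
#'   be ligand names) or a data.frame with `cell_line`, `ligand`,
#'   `responder`.
#' @return data.frame with one labeled row per (cell line, ligand);
#'   attribute `featureCols` lists the simulated feature columns.
#' @export
labeledFeatureSet <- function(features, calls) {
  if ("treatment" %in% names(calls) && !"ligand" %in% names(calls))
    names(calls)[names(calls) == "treatment"] <- "ligand"
  key <- paste(calls$cell_line, calls$ligand)
  if (anyDuplicated(key))
    ltStop("schema", "more than one label per (cell line, ligand)")
  idx <- match(paste(features$cell_line, features$ligand), key)
  if (anyNA(idx))
    ltStop("schema", "missing label for some (cell line, ligand) rows")
  out <- features
  out$label <- calls$responder[idx]
  attr(out, "featureCols") <-
    grep("^(auc|fc|qss)_", names(features), value = TRUE)
  out
}

#' Numeric feature matrix for tree training
#'
#' Simulated features are log10-transformed (floor 1e-12) because
#' receptor inputs span multiple orders of magnitude; the transform is
#' order-preserving, so single-feature threshold splits are unaffected.
#' Mutation flags become 0/1 columns and the ligand identity a one-hot
#' block.
#'
#' @param lfs labeled feature set from [labeledFeatureSet()].
#' @param log10Features logical.
#' @param featureNames optional fixed column order (for prediction).
#' @return list with `X` (matrix), `y` (0/1 integer or NULL), `lines`.
#' @export
featureMatrix <- function(lfs, log10Features = TRUE,
                          featureNames = NULL) {
  fcols <- attr(lfs, "featureCols") %||%
    grep("^(auc|fc|qss)_", names(lfs), value = TRUE)
  Xf <- as.matrix(lfs[fcols])
  if (log10Features) Xf <- log10(pmax(Xf, 1e-12))
  Xm <- cbind(kras_mutant = as.numeric(lfs$kras_mutant),
              pik3ca_mutant = as.numeric(lfs$pik3ca_mutant))
  ligs <- sort(unique(lfs$ligand))
  Xl <- vapply(ligs, function(lg) as.numeric(lfs$ligand == lg),
               numeric(nrow(lfs)))
  if (is.null(dim(Xl))) Xl <- matrix(Xl, nrow = nrow(lfs))
  colnames(Xl) <- paste0("lig_", ligs)
  X <- cbind(Xf, Xm, Xl)
  if (!is.null(featureNames)) {
    missing <- setdiff(featureNames, colnames(X))
    if (length(missing)) {
      add <- matrix(0, nrow(X), length(missing),
                    dimnames = list(NULL, missing))
      X <- cbind(X, add)
    }
    X <- X[, featureNames, drop = FALSE]
  }
  y <- if ("label" %in% names(lfs)) as.integer(lfs$label) else NULL
  list(X = X, y = y, lines = lfs$cell_line)
}

#' Train a single decision tree
#'
#' Greedy recursive partitioning maximizing the signal-to-noise gain
#' (increase in summed squared significance S^2/(S+B) over the children;
#' `criterion = "gini"` reports the same splits with Gini-scaled gains).
#' Ties between equal-gain splits break to the lowest feature index and
#' lowest threshold; all-constant features yield a single-leaf tree.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 integer labels.
#' @param depthLimit maximum depth (root = 0).
#' @param minLeaf minimum rows per leaf.
#' @param criterion `"snr"` or `"gini"`.
#' @return a tree as a list of flat node vectors (class `"snrTree"`).
#' @export
trainTree <- function(X, y, depthLimit = 4, minLeaf = 3,
                      criterion = c("snr", "gini")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  tr <- growTreeCpp(X, as.integer(y), seq_len(nrow(X)) - 1L,
                    as.integer(depthLimit), as.integer(minLeaf),
                    as.integer(criterion == "gini"))
  tr$featureNames <- colnames(X)
  class(tr) <- "snrTree"
  tr
}

#' Predict with a single tree
#' @param tree an `"snrTree"`.
#' @param X feature matrix with the training column order.
#' @return leaf responder fractions per row.
#' @export
predictTree <- function(tree, X) {
  predictTreeCpp(unclass(tree), X)
}

treeGainByFeature <- function(tree, nFeatures) {
  g <- numeric(nFeatures)
  split <- tree$feature >= 0
  if (any(split)) {
    agg <- tapply(tree$gain[split], tree$feature[split] + 1L, sum)
    g[as.integer(names(agg))] <- agg
  }
  g
}

#' Train a bagged ensemble of signal-to-noise trees
#'
#' Each tree is trained on a bootstrap resample of the rows (fraction
#' 1.0 with replacement by default); prediction is the majority vote
#' over trees and importance is the mean split gain per feature over all
#' trees.
#'
#' @param data labeled feature set (data.frame from
#'   [labeledFeatureSet()]) or a numeric matrix (then give `labels`).
#' @param labels 0/1 labels when `data` is a matrix.
#' @param nTrees ensemble size (>= 1).
#' @param bootstrapFraction resample size as a fraction of n.
#' @param replace sample with replacement (bootstrap) or without.
#' @param depthLimit,minLeaf,criterion see [trainTree()].
#' @param log10Features passed to [featureMatrix()] for data.frames.
#' @param seed integer seed (bootstrap draws).
#' @return a [BaggedTreeModel-class].
#' @export
trainBagged <- function(data, labels = NULL, nTrees = 200,
                        bootstrapFraction = 1, replace = TRUE,
                        depthLimit = 4, minLeaf = 3,
                        criterion = c("snr", "gini"),
                        log10Features = TRUE, seed = 1) {
  criterion <- match.arg(criterion)
  if (nTrees < 1) ltStop("precondition", "nTrees must be >= 1")
  if (is.data.frame(data)) {
    fm <- featureMatrix(data, log10Features = log10Features)
    X <- fm$X
    y <- fm$y
    if (is.null(y)) ltStop("schema", "no 'label' column in data")
  } else {
    X <- as.matrix(data)
    y <- as.integer(labels)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  set.seed(as.integer(seed))
  n <- nrow(X)
  m <- max(1L, round(bootstrapFraction * n))
  trees <- vector("list", nTrees)
  gains <- numeric(ncol(X))
  singleClass <- 0L
  for (k in seq_len(nTrees)) {
    rows <- if (bootstrapFraction == 1 && !replace) seq_len(n)
            else sample.int(n, m, replace = replace)
    if (length(unique(y[rows])) < 2) singleClass <- singleClass + 1L
    tr <- growTreeCpp(X, y, rows - 1L, as.integer(depthLimit),
                      as.integer(minLeaf),
                      as.integer(criterion == "gini"))
    trees[[k]] <- tr
    gains <- gains + treeGainByFeature(tr, ncol(X))
  }
  if (singleClass > 0)
    message(singleClass, " bootstrap sample(s) were single-class ",
            "(leaf-only trees)")
  new("BaggedTreeModel", trees = trees,
      featureNames = colnames(X),
      importance = setNames(gains / nTrees, colnames(X)),
      nTrees = as.integer(nTrees), criterion = criterion,
      seed = as.integer(seed),
      params = list(depthLimit = depthLimit, minLeaf = minLeaf,
                    bootstrapFraction = bootstrapFraction,
                    replace = replace, log10Features = log10Features))
}

#' Predict responder status with a bagged ensemble
#'
#' @param object a [BaggedTreeModel-class].
#' @param newdata feature matrix or labeled/unlabeled feature set
#'   data.frame.
#' @param type `"class"` (logical vector) or `"vote"` (vote share).
#' @return logical vector or numeric vote share per row.
#' @export
setMethod("predict", "BaggedTreeModel",
          function(object, newdata, type = c("class", "vote")) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) {
    featureMatrix(newdata,
                  log10Features = object@params$log10Features,
                  featureNames = object@featureNames)$X
  } else {
    as.matrix(newdata)[, object@featureNames, drop = FALSE]
  }
  if (nrow(X) == 0)
    return(if (type == "vote") numeric(0) else logical(0))
  frac <- matrix(vapply(object@trees, function(tr)
    predictTreeCpp(tr, X), numeric(nrow(X))), nrow = nrow(X))
  votes <- rowMeans(frac > 0.5)
  if (type == "vote") return(votes)
  meanFrac <- rowMeans(frac)
  # exact vote ties fall back on the mean leaf fraction
  as.logical(ifelse(abs(votes - 0.5) < 1e-12, meanFrac > 0.5,
                    votes > 0.5))
})

#' @rdname featureImportance
#' @export
setMethod("featureImportance", "BaggedTreeModel",
          function(object, normalize = TRUE) {
  imp <- object@importance
  if (normalize && max(imp) > 0) imp <- imp / max(imp)
  imp
})

setMethod("show", "BaggedTreeModel", function(object) {
  cat("BaggedTreeModel:", object@nTrees, "trees (criterion:",
      object@criterion, ")\n")
  imp <- sort(featureImportance(object), decreasing = TRUE)
  top <- head(imp[imp > 0], 5)
  if (length(top)) {
    cat("  top features:\n")
    for (nm in names(top))
      cat(sprintf("    %-24s %.3f\n", nm, top[nm]))
  }
})

#' Repeated cell-line split evaluation
#'
#' Randomly splits the CELL LINES (all ligand rows of a line stay
#' together, avoiding bias from correlated responses within a line) into
#' training and testing sets `nReps` times; trains a bagged ensemble on
#' all training rows and scores the fraction of true predictions on the
#' held-out lines for the target ligand only (or all ligands for
#' `"combined"`, from which IGF-1 is excluded by default: its responders
#' are too rare for robust prediction).  `control = TRUE` replaces the
#' labels by fair coin flips each repetition, the 50\%-accuracy random
#' control.
#'
#' @param lfs labeled feature set.
#' @param nReps repetitions (default 500).
#' @param trainFraction fraction of lines in the training set.
#' @param targetLigand ligand scored on the test lines, or
#'   `"combined"`.
#' @param excludeIGF1 drop IGF1 rows entirely for `"combined"`.
#' @param nTrees,depthLimit,minLeaf,criterion ensemble hyperparameters.
#' @param log10Features see [featureMatrix()].
#' @param seed integer seed.
#' @param control logical; random-label control.
#' @return a [SplitEvaluation-class].
#' @export
evaluateSplits <- function(lfs, nReps = 500, trainFraction = 0.7,
                           targetLigand = "combined",
                           excludeIGF1 = TRUE, nTrees = 200,
                           depthLimit = 4, minLeaf = 3,
                           criterion = "snr", log10Features = TRUE,
                           seed = 1, control = FALSE) {
  if (targetLigand == "combined" && excludeIGF1)
    lfs <- lfs[lfs$ligand != "IGF1", , drop = FALSE]
  fm <- featureMatrix(lfs, log10Features = log10Features)
  X <- fm$X
  y <- fm$y
  lines <- fm$lines
  ligand <- lfs$ligand
  uLines <- unique(lines)
  nTrain <- max(1L, round(trainFraction * length(uLines)))
  if (nTrain >= length(uLines))
    ltStop("precondition", "trainFraction leaves no test lines")
  set.seed(as.integer(seed))
  acc <- numeric(nReps)
  resampled <- 0L
  for (r in seq_len(nReps)) {
    repeat {
      trLines <- sample(uLines, nTrain)
      testSel <- !(lines %in% trLines) &
        (targetLigand == "combined" | ligand == targetLigand)
      if (any(testSel)) break
      resampled <- resampled + 1L
      if (resampled > 100 * nReps)
        ltStop("precondition", "no test rows for target ligand")
    }
    yr <- if (control) rbinom(length(y), 1, 0.5) else y
    trainSel <- lines %in% trLines
    Xtr <- X[trainSel, , drop = FALSE]
    ytr <- yr[trainSel]
    ens <- trainBaggedFast(Xtr, ytr, nTrees, depthLimit, minLeaf,
                           criterion)
    pred <- predictEnsembleFast(ens, X[testSel, , drop = FALSE])
    acc[r] <- mean(pred == yr[testSel])
  }
  if (resampled > 0)
    message(resampled, " split(s) resampled for lacking test rows")
  new("SplitEvaluation", accuracies = acc,
      targetLigand = targetLigand, nReps = as.integer(nReps),
      trainFraction = trainFraction, seed = as.integer(seed),
      control = control)
}

# lean internal trainers for the repeated-split loop (no S4 packing)
trainBaggedFast <- function(X, y, nTrees, depthLimit, minLeaf,
                            criterion) {
  n <- nrow(X)
  lapply(seq_len(nTrees), function(k)
    growTreeCpp(X, y, sample.int(n, n, replace = TRUE) - 1L,
                as.integer(depthLimit), as.integer(minLeaf),
                as.integer(criterion == "gini")))
}

predictEnsembleFast <- function(trees, X) {
  frac <- matrix(vapply(trees, function(tr)
    predictTreeCpp(tr, X), numeric(nrow(X))), nrow = nrow(X))
  as.integer(rowMeans(frac > 0.5) > 0.5)
}

#' @rdname evaluateSplits
#' @param object a [SplitEvaluation-class].
#' @export
setMethod("accuracies", "SplitEvaluation", function(object) {
  object@accuracies
})

setMethod("show", "SplitEvaluation", function(object) {
  cat("SplitEvaluation (", object@nReps, "repetitions, target:",
      object@targetLigand,
      if (object@control) ", RANDOM CONTROL" else "", ")\n")
  cat(sprintf("  accuracy: mean %.3f, sd %.3f\n",
              mean(object@accuracies), stats::sd(object@accuracies)))
})

#' Paired comparison of two split evaluations
#'
#' One-sided paired Wilcoxon signed-rank test that evaluation `a`
#' achieves higher per-repetition accuracy than evaluation `b`
#' (typically the random control).
#'
#' @param a,b [SplitEvaluation-class] objects with equal repetition
#'   counts.
#' @return one-sided p-value.
#' @export
compareToControl <- function(a, b) {
  x <- accuracies(a)
  y <- accuracies(b)
  if (length(x) != length(y))
    ltStop("pairing", "repetition counts differ")
  if (all(x == y)) return(1)
  suppressWarnings(
    wilcox.test(x, y, paired = TRUE, alternative = "greater",
                exact = FALSE)$p.value)
}
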