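smallDesign <- function() {
  list("EGF@10" = c(EGF = 10), "HRG@10" = c(HRG = 10))
}

test_that("chi-square matches its closed forms", {
  m <- ltModel()
  panel <- makeCellLines(2, seed = 11)
  obsMap <- defaultObservationMap(m)
  # data generated exactly from the model -> zero residuals
  exact <- makeTimecourses(m, panel, obsMap = obsMap,
                           stimuli = smallDesign(), noise = FALSE)
  expect_equal(chiSquare(m, panel, obsMap, exact), 0)

  # a single record off by exactly 2 sigma -> chi-square 4
  df <- exact@data[1, , drop = FALSE]
  df$value <- df$value * exp(2 * df$sigma)  # log-scale offset of 2 sigma
  one <- measurementSet(df, exact@conditions)
  expect_equal(chiSquare(m, panel, obsMap, one), 4, tolerance = 1e-8)

  # unit-sigma noise at the true parameters: chi-square ~ chi2_n
  noisy <- makeTimecourses(m, panel, obsMap = obsMap,
                           stimuli = smallDesign(), seed = 5)
  n <- nrow(noisy@data)
  cs <- chiSquare(m, panel, obsMap, noisy)
  expect_gt(cs, n - 4 * sqrt(2 * n))
  expect_lt(cs, n + 4 * sqrt(2 * n))
})

test_that("chi-square is invariant under joint rescaling of data, scale
           and sigma for linear observables", {
  m <- ltModel()
  panel <- makeCellLines(2, seed = 11)
  obsMap <- observationMap(c("pERK", "pAKT"), scale = 1, offset = 0,
                           sigma = 500, log = FALSE)
  mset <- makeTimecourses(m, panel, obsMap = obsMap,
                          stimuli = smallDesign(), seed = 2)
  cs1 <- chiSquare(m, panel, obsMap, mset)
  c0 <- 7.3
  df <- mset@data
  df$value <- df$value * c0
  df$sigma <- df$sigma * c0
  obsMap2 <- observationMap(c("pERK", "pAKT"), scale = c0, offset = 0,
                            sigma = 500 * c0, log = FALSE)
  cs2 <- chiSquare(m, panel, obsMap2,
                   measurementSet(df, mset@conditions))
  expect_equal(cs1, cs2, tolerance = 1e-10)
})

test_that("fit handles the degenerate declarations per contract", {
  m <- ltModel()
  panel <- makeCellLines(2, seed = 11)
  obsMap <- defaultObservationMap(m)
  mset <- makeTimecourses(m, panel, obsMap = obsMap,
                          stimuli = smallDesign(), seed = 5)
  # empty free set: no-op fit returning chi-square at the supplied theta
  f0 <- fitModel(m, panel, obsMap, mset, free = list())
  expect_equal(f0@chisq, chiSquare(m, panel, obsMap, mset))
  expect_equal(f0@nFree, 0L)
  # zero starts violate the precondition
  expect_error(fitModel(m, panel, obsMap, mset,
                        free = list(kinetics = "het_scale"),
                        nStarts = 0),
               "nStarts")
})

test_that("receptor expression is recovered from synthetic time courses
           and the fit is seed-deterministic", {
  m <- ltModel()
  truth <- makeCellLines(2, seed = 11)
  obsMap <- defaultObservationMap(m)
  stim <- defaultStimulusDesign(ligands = c("EGF", "HRG", "HGF",
                                            "IGF1"),
                                doses = c(0.625, 10), coDose = NULL)
  mset <- makeTimecourses(m, truth, obsMap = obsMap, stimuli = stim,
                          seed = 7)
  nominal <- as.data.frame(truth)
  nominal[, c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")] <- 1e5
  nomPanel <- cellLinePanel(nominal)
  fit <- fitModel(m, nomPanel, obsMap, mset,
                  free = list(receptors = cellLines(truth)),
                  nStarts = 6, seed = 3, maxiter = 25)
  recs <- c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")
  tru <- as.matrix(as.data.frame(truth)[, recs])
  est <- as.matrix(as.data.frame(fit@contexts)[, recs])
  expect_lt(max(abs(est - tru) / tru), 0.20)
  expect_lte(fit@chisq, chiSquare(m, truth, obsMap, mset))

  fit2 <- fitModel(m, nomPanel, obsMap, mset,
                   free = list(receptors = cellLines(truth)),
                   nStarts = 6, seed = 3, maxiter = 25)
  expect_identical(fit@theta, fit2@theta)
})

test_that("holdout prediction guards leakage and degrades under
           receptor swaps", {
  m <- ltModel()
  panel <- makeCellLines(4, seed = 21)
  df <- as.data.frame(panel)
  trainPanel <- cellLinePanel(df[1:3, , drop = FALSE])
  holdPanel <- cellLinePanel(df[4, , drop = FALSE])
  obsMap <- defaultObservationMap(m, observables = c("pEGFR", "pERK",
                                                     "pAKT"))
  train <- makeTimecourses(m, trainPanel, obsMap = obsMap,
                           stimuli = smallDesign(), seed = 2)
  hold <- makeTimecourses(m, holdPanel, obsMap = obsMap,
                          stimuli = smallDesign(), seed = 3)
  fit <- fitModel(m, trainPanel, obsMap, train, free = list())

  expect_error(predictHoldout(fit, m, trainPanel, obsMap, train,
                              line = df$cell_line[1]),
               "overlaps the training set")
  empty <- measurementSet(hold@data[0, ], hold@conditions)
  rep0 <- predictHoldout(fit, m, holdPanel, obsMap, empty)
  expect_equal(rep0$n, 0L)

  rep1 <- predictHoldout(fit, m, holdPanel, obsMap, hold)
  # same generating parameters: holdout chi2/n close to training chi2/n
  expect_lt(rep1$chisqPerN, 2 * fit@chisq / fit@nPoints)

  # non-matching receptor levels from other lines fit worse on average
  set.seed(9)
  swapped <- vapply(1:20, function(i) {
    wrong <- df[4, ]
    src <- df[sample(1:3, 1), ]
    wrong[, c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")] <-
      src[, c("EGFR", "HER2", "ErbB3", "Met", "IGF1R")] *
      runif(5, 0.5, 2)
    wrong$cell_line <- df$cell_line[4]
    predictHoldout(fit, m, cellLinePanel(wrong), obsMap,
                   hold)$chisqPerN
  }, 0)
  expect_gt(mean(swapped), rep1$chisqPerN)
})

test_that("the likelihood-ratio test follows its contracts", {
  f <- new("FitResult", theta = c(a = 1), params = defaultKinetics(),
           contexts = makeCellLines(2, seed = 1), chisq = 100,
           nPoints = 50L, nFree = 3L, starts = data.frame(),
           seed = 1L, trainLines = "x")
  r <- f; r@nFree <- 1L; r@chisq <- 100
  # identical chi-squares -> statistic 0, p = 1
  out <- lrtReduced(f, r)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  expect_equal(out$df, 2L)
  # reduced better than full -> validity error
  r2 <- r; r2@chisq <- 90
  expect_error(lrtReduced(f, r2), "not nested")
  # boundary correction halves the tail probability (df = 1)
  r3 <- r; r3@chisq <- 105; r3@nFree <- 2L
  pb <- lrtReduced(f, r3, boundary = TRUE)$p.value
  expect_equal(pb, 0.5 * pchisq(5, 1, lower.tail = FALSE))
  expect_error(lrtReduced(f, r, boundary = TRUE), "df = 1")
})

test_that("coverage fraction matches its limits and the Gaussian
           expectation", {
  m <- ltModel()
  panel <- makeCellLines(2, seed = 11)
  obsMap <- defaultObservationMap(m)
  exact <- makeTimecourses(m, panel, obsMap = obsMap,
                           stimuli = smallDesign(), noise = FALSE)
  expect_equal(coverageFraction(m, panel, obsMap, exact), 1.0)
  expect_error(coverageFraction(m, panel, obsMap, exact, k = 0),
               "k must be > 0")
  noisy <- makeTimecourses(m, panel, obsMap = obsMap,
                           stimuli = smallDesign(), seed = 5)
  n <- nrow(noisy@data)
  cov2 <- coverageFraction(m, panel, obsMap, noisy, k = 2)
  expect_lt(abs(cov2 - 0.9545), 4 * sqrt(0.9545 * 0.0455 / n))
  expect_lt(coverageFraction(m, panel, obsMap, noisy, k = 1e-6), 0.01)
})
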