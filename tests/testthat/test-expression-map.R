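test_that("the mRNA-to-surface linear map recovers power laws", {
  set.seed(3)
  mrna <- 10^runif(40, 0, 3)
  b <- 0.8; a <- 2.5
  surface <- 10^(a + b * log10(mrna) + rnorm(40, 0, 0.15))
  pairs <- data.frame(receptor = "EGFR", mrna = mrna,
                      surface = surface)
  map <- fitLinearMap(pairs)
  cf <- map@coefs
  expect_lt(abs(cf$slope - b), 0.15)
  expect_gt(cf$r_squared, 0.8)

  # exact power law: zero residuals (r^2 = 1)
  exact <- data.frame(receptor = "Met", mrna = mrna,
                      surface = 10^(1 + 1.2 * log10(mrna)))
  cfe <- fitLinearMap(exact)@coefs
  expect_equal(cfe$r_squared, 1)
  expect_equal(predictSurface(fitLinearMap(exact), "Met", 100),
               10^(1 + 1.2 * 2), tolerance = 1e-8)

  expect_error(fitLinearMap(data.frame(receptor = "EGFR",
                                       mrna = c(1, 2),
                                       surface = c(10, 20))),
               ">= 3")
  expect_message(fitLinearMap(rbind(pairs,
    data.frame(receptor = "EGFR", mrna = 0, surface = 5))),
    "filtered")
})

test_that("cohort prediction is scale-invariant, respects degenerate
           inputs, and tracks the planted fraction", {
  m <- ltModel()
  panelRef <- loadCellLinePanel()
  co <- makeCohort(m, nSamples = 80, responderFraction = 0.4,
                   ligand = "HRG", ligandShift = 1, seed = 4)
  # train an ensemble on the planted truth of the same cohort features
  lab <- data.frame(cell_line = co$features$cell_line,
                    ligand = co$features$ligand,
                    responder = co$planted)
  lfs <- labeledFeatureSet(co$features, lab)
  ens <- trainBagged(lfs, nTrees = 60, seed = 2)

  pred <- cohortPredict(co$expr, m, ens, "HRG", panelRef = panelRef)
  expect_equal(nrow(pred), 80L)
  frac <- attr(pred, "responderFraction")
  expect_lt(abs(frac - 0.4), 0.10)

  # multiplying the whole table by a constant changes nothing
  pred2 <- cohortPredict(co$expr * 37, m, ens, "HRG",
                         panelRef = panelRef)
  expect_identical(pred$responder, pred2$responder)

  # all-identical samples -> identical predictions
  same <- co$expr[rep(1, 6), ]
  rownames(same) <- paste0("S", 1:6)
  predSame <- cohortPredict(same, m, ens, "HRG", panelRef = panelRef)
  expect_equal(length(unique(predSame$responder)), 1L)

  # empty cohort -> empty output
  expect_equal(nrow(cohortPredict(co$expr[0, ], m, ens, "HRG",
                                  panelRef = panelRef)), 0L)

  # missing gene -> schema error naming it
  expect_error(cohortPredict(co$expr[, setdiff(colnames(co$expr),
                                               "MET")],
                             m, ens, "HRG", panelRef = panelRef),
               "MET")
})

test_that("ligand association detects planted shifts and is calibrated
           under the null", {
  m <- ltModel()
  co <- makeCohort(m, nSamples = 240, responderFraction = 0.5,
                   ligand = "HRG", ligandShift = 1, seed = 6)
  hit <- ligandAssociation(co$expr, co$planted, co$ligandGene)
  expect_lt(hit$p.value, 0.01)
  expect_gt(hit$meanDiff, 0.5)

  # permutation null: rejection rate ~ alpha
  set.seed(9)
  null <- makeCohort(m, nSamples = 240, responderFraction = 0.5,
                     ligand = "HRG", ligandShift = 0, seed = 7)
  ps <- vapply(1:200, function(i)
    ligandAssociation(null$expr, sample(null$planted),
                      null$ligandGene)$p.value, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)

  # identical distributions at scale: mean difference near zero
  expect_lt(abs(ligandAssociation(null$expr, null$planted,
                                  null$ligandGene)$meanDiff), 0.3)

  # single-class predictions are an error
  expect_error(ligandAssociation(co$expr, rep(TRUE, 240),
                                 co$ligandGene), "non-empty")
})
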