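test_that("network specs satisfy their structural invariants", {
  sp <- rtkModelSpec("full")
  expect_equal(nrow(sp@dimers), 10L)
  expect_setequal(
    dimerNames(sp),
    c("EGFR:EGFR", "HER2:HER2", "ErbB3:ErbB3", "Met:Met", "IGF1R:IGF1R",
      "EGFR:HER2", "EGFR:ErbB3", "EGFR:Met", "HER2:ErbB3", "ErbB3:Met"))
  e3 <- sp@dimers$recA == "ErbB3" & sp@dimers$recB == "ErbB3"
  expect_false(sp@dimers$signaling[e3])

  # the IGF-1R heterodimer-removal alias resolves to the 10-dimer model
  expect_equal(modelVariant(rtkModelSpec("no_igf1r_heterodimers")),
               "full")

  sp12 <- rtkModelSpec("with_igf1r_heterodimers")
  expect_equal(nrow(sp12@dimers), 12L)
  expect_true(all(c("EGFR:IGF1R", "HER2:IGF1R") %in% dimerNames(sp12)))

  sp5 <- rtkModelSpec("no_heterodimers")
  expect_equal(nrow(sp5@dimers), 5L)
  expect_true(all(sp5@dimers$recA == sp5@dimers$recB))
  expect_true(all(sp5@dimers$signaling))

  # duplicate dimers under pair symmetry are rejected
  bad <- sp
  bad@dimers <- rbind(sp@dimers,
                      data.frame(recA = "HER2", recB = "EGFR",
                                 signaling = TRUE))
  expect_error(validObject(bad), "duplicate")
})

test_that("buildModel validates parameters and reports a stable state
           inventory", {
  m <- ltModel()
  expect_equal(nStates(m), 35L)
  expect_identical(stateNames(m), stateNames(buildModel()))
  expect_equal(length(observableNames(m)), 9L + 5L + 5L)
  expect_equal(nStates(ltModelNoHet()), 25L)

  p <- defaultKinetics()
  expect_error(buildModel(rtkModelSpec("full"), p[-1]),
               "missing kinetic parameter")
  p2 <- p
  p2["kint_EGFR:EGFR"] <- 0
  expect_error(buildModel(rtkModelSpec("full"), p2), "must be > 0")
  p3 <- p
  p3["wMAPK_ErbB3:ErbB3"] <- 0.5
  expect_error(buildModel(rtkModelSpec("full"), p3), "non-signaling")
})

test_that("basal steady state meets the residual contract and responds
           monotonically to receptor expression", {
  m <- ltModel()
  ss <- steadyState(m, demoContext())
  expect_lt(ss$residual, 1e-8)
  expect_equal(unname(ss$x0[c("EGFR", "HER2")]), c(2e5, 1e5))

  # empty system: all receptors zero -> every state zero
  ss0 <- steadyState(m, list(name = "empty",
                             receptors = c(EGFR = 0, HER2 = 0,
                                           ErbB3 = 0, Met = 0,
                                           IGF1R = 0)))
  expect_true(all(ss0$x0 == 0))

  # basal pEGFR (phospho-dimer pools holding EGFR) grows with EGFR
  grid <- c(1e4, 1e5, 1e6)
  basal <- vapply(grid, function(e) {
    ctx <- demoContext()
    ctx$receptors["EGFR"] <- e
    x0 <- steadyState(m, ctx)$x0
    2 * (x0[["pD.EGFR.EGFR.s"]] + x0[["pD.EGFR.EGFR.i"]]) +
      x0[["pD.EGFR.HER2.s"]] + x0[["pD.EGFR.HER2.i"]]
  }, 0)
  expect_true(all(diff(basal) > 0))

  # doubling all receptors strictly raises every signaling dimer pool
  ssA <- steadyState(m, demoContext())
  ssB <- steadyState(m, demoContext(scale = 2))
  sPools <- grep("^pD\\..*\\.s$", names(ssA$x0), value = TRUE)
  expect_true(all(ssB$x0[sPools] > ssA$x0[sPools]))
})

test_that("ligand-free simulation stays on the steady state and states
           remain non-negative", {
  m <- ltModel()
  ss <- steadyState(m, demoContext())
  tr0 <- simulateTrajectory(m, demoContext(), ss = ss)
  dev <- abs(sweep(tr0@states, 2, ss$x0, "-")) /
    matrix(pmax(1, abs(ss$x0)), nrow(tr0@states), ncol(tr0@states),
           byrow = TRUE)
  expect_lt(max(dev), 1e-6)

  tr <- simulateTrajectory(m, demoContext(), doses = c(EGF = 10,
                                                       HRG = 10))
  expect_true(all(tr@states >= -1e-9))
  expect_true(all(tr@observables >= -1e-9))
})

test_that("receptor copies are conserved when turnover is switched
           off", {
  p <- defaultKinetics()
  p["kdeg_R"] <- 0
  p[grep("^kxdeg_", names(p))] <- 0
  m <- buildModel(rtkModelSpec("full"), p)
  x0 <- steadyState(ltModel(), demoContext())$x0
  for (doses in list(c(EGF = 10), c(HRG = 10), c(HGF = 10),
                     c(IGF1 = 10))) {
    tr <- simulateFromState(m, x0, doses = doses,
                            synthesis = rep(0, 5))
    tot <- receptorTotals(m, tr)
    rel <- abs(sweep(tot, 2, tot[1, ], "-")) /
      matrix(tot[1, ], nrow(tot), ncol(tot), byrow = TRUE)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("EGFR-high and EGFR-low contexts show sustained versus
           transient receptor phosphorylation", {
  m <- ltModel()
  hi <- list(name = "hi", receptors = c(EGFR = 1.2e6, HER2 = 8e4,
                                        ErbB3 = 2e4, Met = 3e4,
                                        IGF1R = 3e4))
  lo <- list(name = "lo", receptors = c(EGFR = 1.9e4, HER2 = 4.8e4,
                                        ErbB3 = 1.7e4, Met = 3e4,
                                        IGF1R = 3e4))
  sh <- simulateTrajectory(m, hi, doses = c(EGF = 10))@observables[, "pEGFR"]
  sl <- simulateTrajectory(m, lo, doses = c(EGF = 10))@observables[, "pEGFR"]
  lateOverPeakHi <- sh[length(sh)] / max(sh)
  lateOverPeakLo <- sl[length(sl)] / max(sl)
  expect_gt(lateOverPeakHi, lateOverPeakLo + 0.05)
  # the low-EGFR context peaks early
  expect_lt(which.max(sl), which.max(sh))
})

test_that("EGF+HRG co-stimulation reduces phospho-ErbB3 relative to HRG
           alone in an EGFR-high context", {
  m <- ltModel()
  hi <- list(name = "hi", receptors = c(EGFR = 1.2e6, HER2 = 8e4,
                                        ErbB3 = 2e4, Met = 3e4,
                                        IGF1R = 3e4))
  co <- simulateTrajectory(m, hi,
                           doses = c(EGF = 2.5, HRG = 2.5))
  alone <- simulateTrajectory(m, hi, doses = c(HRG = 2.5))
  i30 <- which(defaultTimeGrid() == 30)
  expect_lt(co@observables[i30, "pErbB3"],
            alone@observables[i30, "pErbB3"])
})

test_that("the non-signaling ErbB3 homodimer contributes zero flux to
           the cascade inputs", {
  m <- ltModel()
  ss <- steadyState(m, demoContext())
  ptr <- ligandtree:::packParms(m, unname(ss$synthesis))
  x <- unname(ss$x0)
  base <- ligandtree:::cascadeInputCpp(ptr, x)
  idx <- match(c("D.ErbB3.ErbB3.s", "D.ErbB3.ErbB3.i"), stateNames(m))
  x[idx] <- x[idx] * 1e6 + 1e5
  bumped <- ligandtree:::cascadeInputCpp(ptr, x)
  expect_identical(base, bumped)
})

test_that("zeroing the IGF-1R heterodimer association rates reproduces
           the variant without those dimers", {
  sp12 <- rtkModelSpec("with_igf1r_heterodimers")
  p12 <- defaultKinetics(sp12)
  p12[c("kasc_EGFR:IGF1R", "kasc_HER2:IGF1R")] <- 0
  m12 <- buildModel(sp12, p12)
  m10 <- ltModel()
  tr12 <- simulateTrajectory(m12, demoContext(),
                             doses = c(EGF = 5, IGF1 = 10))
  tr10 <- simulateTrajectory(m10, demoContext(),
                             doses = c(EGF = 5, IGF1 = 10))
  shared <- intersect(colnames(tr12@observables),
                      colnames(tr10@observables))
  expect_lt(max(abs(tr12@observables[, shared] -
                    tr10@observables[, shared]) /
                pmax(1, abs(tr10@observables[, shared]))), 1e-8)
})

test_that("SBML export round-trips the state inventory", {
  m <- ltModel()
  path <- tempfile(fileext = ".xml")
  exportSBML(m, path)
  s <- readSBMLSummary(path)
  expect_equal(s$nSpecies, nStates(m))
  expect_gt(s$nReactions, 0)

  m5 <- ltModelNoHet()
  path5 <- tempfile(fileext = ".xml")
  exportSBML(m5, path5)
  s5 <- readSBMLSummary(path5)
  expect_equal(s5$nSpecies, nStates(m5))
  # 5 dimers -> 5 surface + 5 internal dimer species pools
  expect_equal(sum(grepl("^p?D_", s5$speciesIds)), 10L)

  expect_error(exportSBML(m, file.path(tempdir(), "nope", "x.xml")),
               "no such directory")
})
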