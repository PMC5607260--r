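fakeTrajectory <- function(time, values, species = "pERK") {
  obs <- matrix(values, ncol = 1, dimnames = list(NULL, species))
  new("Trajectory", time = time, states = obs, observables = obs,
      cellLine = "fake", doses = c(EGF = 1))
}

test_that("AUC matches closed forms and refines stably", {
  tt <- seq(0, 100, by = 10)
  # constant c over [0, T] -> c * T
  trC <- fakeTrajectory(tt, rep(3.5, length(tt)))
  expect_equal(aucFeature(trC, "pERK"), 3.5 * 100)
  # linear ramp 0 -> c -> c * T / 2
  trL <- fakeTrajectory(tt, 7 * tt / 100)
  expect_equal(aucFeature(trL, "pERK"), 7 * 100 / 2)
  # window subsetting with interpolation
  expect_equal(aucFeature(trC, "pERK", 5, 95), 3.5 * 90)
  expect_error(aucFeature(trC, "pERK", -1, 50), "grid span")
  expect_error(aucFeature(trC, "nope"), "unknown species")

  # grid refinement changes the AUC of a smooth trajectory by < 1%
  m <- ltModel()
  coarse <- simulateTrajectory(m, demoContext(), doses = c(EGF = 10))
  t2 <- sort(unique(c(defaultTimeGrid(),
                      head(defaultTimeGrid(), -1) +
                        diff(defaultTimeGrid()) / 2)))
  fine <- simulateTrajectory(m, demoContext(), doses = c(EGF = 10),
                             times = t2)
  a1 <- aucFeature(coarse, "pERK")
  a2 <- aucFeature(fine, "pERK", 0, 240)
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("the feature table has one 12-feature row per (line, ligand)
           and is deterministic", {
  m <- ltModel()
  panel <- loadCellLinePanel()
  ft <- featureTable(m, panel)
  expect_equal(nrow(ft), 58L * 4L)
  expect_equal(sum(grepl("^auc_", names(ft))), 12L)
  expect_true(all(c("kras_mutant", "pik3ca_mutant") %in% names(ft)))
  expect_true(all(as.matrix(ft[grep("^auc_", names(ft))]) >= 0))

  # duplicate contexts give identical rows
  df <- as.data.frame(panel)[1:2, ]
  dup <- df
  dup$cell_line <- paste0(df$cell_line, "_copy")
  both <- cellLinePanel(rbind(df, dup))
  ft2 <- featureTable(m, both, ligands = "EGF")
  aucCols <- grep("^auc_", names(ft2))
  expect_equal(unname(as.matrix(ft2[1:2, aucCols])),
               unname(as.matrix(ft2[3:4, aucCols])))

  # all-zero receptors: every AUC equals the zero baseline integral
  zero <- cellLinePanel(data.frame(
    cell_line = "Z", kras_mutant = FALSE, pik3ca_mutant = FALSE,
    EGFR = 0, HER2 = 0, ErbB3 = 0, Met = 0, IGF1R = 0))
  ftz <- featureTable(m, zero, ligands = "EGF")
  expect_true(all(as.matrix(ftz[grep("^auc_", names(ftz))]) == 0))
})

test_that("ligand specificity and monotone dose response hold", {
  m <- ltModel()
  ctx <- demoContext()
  ss <- steadyState(m, ctx)
  basalTraj <- simulateTrajectory(m, ctx, ss = ss)
  basalMet <- aucFeature(basalTraj, "pD_Met_Met")
  egfTraj <- simulateTrajectory(m, ctx, doses = c(EGF = 5), ss = ss)
  egfMet <- aucFeature(egfTraj, "pD_Met_Met")
  stimChange <- aucFeature(egfTraj, "pD_EGFR_EGFR") -
    aucFeature(basalTraj, "pD_EGFR_EGFR")
  # EGF moves the Met homodimer only via shared-pool competition
  expect_lt(abs(egfMet - basalMet), 0.01 * abs(stimChange))

  aucs <- vapply(c(0.156, 0.625, 2.5, 10), function(d)
    aucFeature(simulateTrajectory(m, ctx, doses = c(EGF = d),
                                  ss = ss), "pD_EGFR_EGFR"), 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("fold-change and quasi-steady-state extras are emitted on
           demand", {
  m <- ltModel()
  panel <- cellLinePanel(as.data.frame(loadCellLinePanel())[1:2, ])
  ft <- featureTable(m, panel, ligands = "EGF", extras = TRUE)
  expect_equal(sum(grepl("^fc_", names(ft))), 12L)
  expect_equal(sum(grepl("^qss_", names(ft))), 12L)
  expect_true(all(as.matrix(ft[grep("^fc_", names(ft))]) >= 1 - 1e-9))
})
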