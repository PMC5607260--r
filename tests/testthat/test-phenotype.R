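test_that("the exact Wilcoxon rank-sum test matches enumeration", {
  # identical replicate vectors: rank sum sits at its mean -> p = 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3, 4), c(1, 2, 3, 4))$p.value, 1)
  # complete 4-vs-4 separation: 2 of the 70 assignments are as extreme
  expect_equal(wilcoxonRankSum(c(5, 6, 7, 8), c(1, 2, 3, 4))$p.value,
               2 / 70)
  # 3-vs-3 separation cannot reach 0.05: p = 2/20
  expect_equal(wilcoxonRankSum(c(4, 5, 6), c(1, 2, 3))$p.value, 2 / 20)
  expect_error(wilcoxonRankSum(c(1), c(1, 2)), "length >= 2")

  # cross-check against stats::wilcox.test (exact, tie-free) and the
  # brute-force enumeration oracle on random quadruplicates
  set.seed(42)
  for (i in 1:25) {
    a <- round(rnorm(4, 10, 3), 4)
    b <- round(rnorm(4, 11, 3), 4)
    p <- wilcoxonRankSum(a, b)$p.value
    expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(p, wilcoxEnumOracle(a, b), tolerance = 1e-12)
  }
  # ties fall back to mid-ranks (message) and agree with the oracle
  a <- c(1, 2, 2, 5); b <- c(2, 3, 4, 4)
  expect_message(p <- wilcoxonRankSum(a, b)$p.value, "mid-ranks")
  expect_equal(p, wilcoxEnumOracle(a, b))
})

test_that("responder calls combine the 20% threshold with the exact
           test", {
  ref <- list(cell_line = "L1", treatment = "medium",
              day0 = rep(1000, 4), day3 = c(2950, 3000, 3020, 3060))
  mk <- function(day3) list(cell_line = "L1", treatment = "EGF",
                            day0 = rep(1000, 4), day3 = day3)
  # 1.31x control with clean separation: responder (p = 2/70)
  up <- callResponder(mk(c(3900, 3930, 3960, 3990)), ref)
  expect_true(up$responder)
  expect_equal(up$p_value, 2 / 70, tolerance = 1e-12)
  # 1.15x control: below the threshold regardless of p
  mid <- callResponder(mk(c(3430, 3450, 3470, 3490)), ref)
  expect_false(mid$responder)
  expect_gt(mid$ratio, 1.1)
  # 1.5x control on average but overlapping replicates: not significant
  ov <- callResponder(mk(c(2500, 2800, 5000, 7700)), ref)
  expect_false(ov$responder)
  expect_gte(ov$p_value, 0.05)
  # mismatched cell lines -> pairing error
  bad <- mk(c(4000, 4100, 4200, 4300)); bad$cell_line <- "L2"
  expect_error(callResponder(bad, ref), "different cell lines")
})

test_that("the mirrored inhibition rule and scaling invariance hold", {
  ref <- list(cell_line = "L1", treatment = "EGF",
              day0 = rep(1000, 4), day3 = c(2950, 3000, 3020, 3060))
  inh <- list(cell_line = "L1", treatment = "EGF+mAb",
              day0 = rep(1000, 4), day3 = c(2100, 2150, 2200, 2250))
  down <- callResponder(inh, ref, direction = "decrease")
  expect_true(down$responder)

  scale <- function(r, c0) {
    r$day0 <- r$day0 * c0; r$day3 <- r$day3 * c0; r
  }
  for (c0 in c(0.01, 17)) {
    expect_equal(callResponder(scale(inh, c0), scale(ref, c0),
                               direction = "decrease")$responder,
                 down$responder)
  }
})

test_that("no responder call ever carries p >= alpha across a whole
           synthetic screen", {
  labels <- data.frame(
    cell_line = rep(sprintf("L%02d", 1:12), each = 2),
    ligand = rep(c("EGF", "HRG"), 12),
    responder = rep(c(TRUE, FALSE), 12))
  viab <- makeViability(labels, seed = 3)
  calls <- callResponders(viab)
  expect_true(all(calls$p_value[calls$responder] < 0.05))
  expect_true(all(calls$ratio[calls$responder] > 1.2))
  # quadruplicates: every responder call needs near-complete separation
  expect_true(all(calls$p_value[calls$responder] >= 2 / 70 - 1e-12))
})

test_that("noise-free screens recover planted labels exactly and the
           threshold sweep reproduces them across 10-30%", {
  labels <- data.frame(
    cell_line = rep(sprintf("L%02d", 1:10), each = 2),
    ligand = rep(c("EGF", "HRG"), 10),
    responder = rep(c(TRUE, FALSE, FALSE, TRUE), 5))
  viab <- makeViability(labels, cv = 0, labelNoise = 0, seed = 1)
  calls <- callResponders(viab)
  key <- paste(calls$cell_line, calls$treatment)
  planted <- labels$responder[match(key, paste(labels$cell_line,
                                               labels$ligand))]
  expect_identical(calls$responder, planted)

  # a 15% effect never crosses the 20% threshold
  v15 <- makeViability(labels, effect = 0.15, cv = 0, labelNoise = 0,
                       seed = 1)
  expect_false(any(callResponders(v15)$responder))

  sweep <- thresholdSweep(viab)
  agree <- tapply(sweep$responder == planted[match(
    paste(sweep$cell_line, sweep$treatment), key)], sweep$threshold,
    mean)
  # a 30% planted effect stays callable over the 10-30% band
  expect_true(all(agree[c("1.1", "1.15", "1.2", "1.25")] == 1))
})
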