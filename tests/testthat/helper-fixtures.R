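# Shared fixtures: one compiled model per variant and a couple of
# deterministic contexts, built once per test run.

ltModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildModel()
    cache
  }
})

ltModelNoHet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- rtkModelSpec("no_heterodimers")
      cache <<- buildModel(sp, defaultKinetics(sp))
    }
    cache
  }
})

demoContext <- function(scale = 1) {
  list(name = "demo",
       receptors = scale * c(EGFR = 2e5, HER2 = 1e5, ErbB3 = 3e4,
                             Met = 4e4, IGF1R = 3e4))
}

# independent brute-force Wilcoxon oracle: enumerate every assignment of
# the pooled values to the two groups and count rank sums at least as
# extreme as observed
wilcoxEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n <- length(pooled)
  na <- length(a)
  mu <- na * (n + 1) / 2
  Wobs <- sum(rk[seq_len(na)])
  sets <- combn(n, na)
  Wall <- colSums(matrix(rk[sets], nrow = na))
  mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-9)
}

# small labeled feature set with a planted single-feature rule
plantedLabeledSet <- function(nLines = 24, seed = 1, noise = 0,
                              ligands = c("EGF", "HRG")) {
  set.seed(seed)
  rows <- expand.grid(cell_line = sprintf("L%02d", seq_len(nLines)),
                      ligand = ligands, stringsAsFactors = FALSE)
  n <- nrow(rows)
  rows$kras_mutant <- rep(runif(nLines) < 0.3, length(ligands))
  rows$pik3ca_mutant <- rep(runif(nLines) < 0.3, length(ligands))
  rows$auc_signal <- 10^runif(n, 3, 7)
  rows$auc_noise1 <- 10^runif(n, 3, 7)
  rows$auc_noise2 <- 10^runif(n, 3, 7)
  lab <- rows$auc_signal > median(rows$auc_signal)
  if (noise > 0) lab <- xor(lab, runif(n) < noise)
  rows$label <- lab
  attr(rows, "featureCols") <- c("auc_signal", "auc_noise1",
                                 "auc_noise2")
  rows
}
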