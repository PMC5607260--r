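# Shared kinetic parameter set.  Units: time min^-1, ligand doses nM,
# receptor/protein abundances molecules/cell; bimolecular dimerization
# rates are per (molecules/cell) per min, so no volume conversion is
# applied anywhere (binding rates absorb the unit choice).

downstreamDefaults <- function() {
  c(
    MEK_total = 1e5, ERK_total = 2e5, AKT_total = 1e5,
    S6K1_total = 1e5, S6_total = 2e5,
    ka_MEK = 1e-5, kd_MEK = 0.30,
    ka_ERK = 5e-6, kd_ERK = 0.30,
    ka_AKT = 1e-5, kd_AKT = 0.30,
    ka_S6K1_ERK = 1e-6, ka_S6K1_AKT = 2e-6, kd_S6K1 = 0.20,
    ka_S6 = 2e-6, kd_S6 = 0.20,
    kfb_ERK = 5e-5, kfb_S6K1 = 5e-5
  )
}

# per-dimer trafficking defaults; HER2-containing dimers internalize
# slowly, ligand-driven EGFR homodimers internalize and degrade fast
dimerRateDefaults <- function(dn) {
  # HER2 is the preferred dimerization partner; its strong pairing with
  # ligand-bound EGFR lets EGF deplete free HER2 and thereby reduce
  # HER2:ErbB3 formation under EGF+HRG co-stimulation
  kasc <- c("EGFR:EGFR" = 2e-7, "HER2:HER2" = 1e-7, "ErbB3:ErbB3" = 1e-7,
            "Met:Met" = 2e-7, "IGF1R:IGF1R" = 2e-7,
            "EGFR:HER2" = 8e-7, "EGFR:ErbB3" = 5e-8, "EGFR:Met" = 2e-7,
            "HER2:ErbB3" = 4e-7, "ErbB3:Met" = 2e-7,
            "EGFR:IGF1R" = 1e-7, "HER2:IGF1R" = 1e-7)
  # trafficking asymmetry (homodimer pools turn over slowly, the
  # EGFR:HER2 heterodimer fast) reproduces the sustained receptor
  # phosphorylation of EGFR-high lines versus the transient, early
  # activation of lines whose scarce EGFR is consumed by heterodimers
  kint <- c("EGFR:EGFR" = 0.02, "HER2:HER2" = 0.02, "ErbB3:ErbB3" = 0.03,
            "Met:Met" = 0.05, "IGF1R:IGF1R" = 0.04,
            "EGFR:HER2" = 0.09, "EGFR:ErbB3" = 0.05, "EGFR:Met" = 0.06,
            "HER2:ErbB3" = 0.025, "ErbB3:Met" = 0.04,
            "EGFR:IGF1R" = 0.03, "HER2:IGF1R" = 0.03)
  kx <- c("EGFR:EGFR" = 0.008, "HER2:HER2" = 0.01, "ErbB3:ErbB3" = 0.01,
          "Met:Met" = 0.01, "IGF1R:IGF1R" = 0.01,
          "EGFR:HER2" = 0.02, "EGFR:ErbB3" = 0.01, "EGFR:Met" = 0.015,
          "HER2:ErbB3" = 0.01, "ErbB3:Met" = 0.01,
          "EGFR:IGF1R" = 0.01, "HER2:IGF1R" = 0.01)
  # pathway weights: EGFR/Met couple mainly to MAPK, ErbB3 (six PI3K
  # docking sites) and IGF1R mainly to PI3K
  wM <- c("EGFR:EGFR" = 1.0, "HER2:HER2" = 0.8, "ErbB3:ErbB3" = 0,
          "Met:Met" = 1.0, "IGF1R:IGF1R" = 0.2,
          "EGFR:HER2" = 1.2, "EGFR:ErbB3" = 0.6, "EGFR:Met" = 1.0,
          "HER2:ErbB3" = 0.8, "ErbB3:Met" = 0.5,
          "EGFR:IGF1R" = 0.3, "HER2:IGF1R" = 0.3)
  wP <- c("EGFR:EGFR" = 0.2, "HER2:HER2" = 0.2, "ErbB3:ErbB3" = 0,
          "Met:Met" = 0.6, "IGF1R:IGF1R" = 1.0,
          "EGFR:HER2" = 0.3, "EGFR:ErbB3" = 1.0, "EGFR:Met" = 0.5,
          "HER2:ErbB3" = 1.2, "ErbB3:Met" = 1.0,
          "EGFR:IGF1R" = 0.6, "HER2:IGF1R" = 0.6)
  list(kasc = kasc[dn], kint = kint[dn], kx = kx[dn],
       wM = wM[dn], wP = wP[dn])
}

#' Default shared kinetic parameter set
#'
#' Literature-plausible magnitudes: ligand on-rates of 0.06 /nM/min
#' (~1e6 /M/s) with dissociation constants of order 0.5--2 nM, receptor
#' half-lives of hours, dimer internalization on the minutes scale, and
#' downstream phosphorylation turnover of 0.2--0.3 /min.  All kinetics are
#' shared across cell lines; only receptor expression differs per line.
#' Betacellulin (BTC) re-uses the EGF machinery but with per-ligand
#' dimerization multipliers that favor the EGFR homodimer over the
#' EGFR:HER2 heterodimer.
#'
#' @param spec an [RTKModelSpec-class].
#' @return named numeric vector covering every reaction the spec implies.
#' @export
defaultKinetics <- function(spec = rtkModelSpec("full")) {
  dn <- dimerNames(spec)
  dr <- dimerRateDefaults(dn)
  sig <- spec@dimers$signaling
  wM <- ifelse(sig, dr$wM, 0)
  wP <- ifelse(sig, dr$wP, 0)
  if (spec@variant == "no_heterodimers") {
    # reduced network: ErbB3 signals through its homodimer
    e3 <- dn == "ErbB3:ErbB3"
    wM[e3] <- 0.3
    wP[e3] <- 1.2
  }
  lig <- spec@ligands$ligand
  kon <- setNames(rep(0.06, length(lig)), paste0("kon_", lig))
  kdv <- c(EGF = 2.0, HRG = 1.0, HGF = 0.5, IGF1 = 1.5, BTC = 1.0)
  KD <- setNames(kdv[lig], paste0("KD_", lig))
  p <- c(
    f_spont = 0.02, kdeg_R = 0.005, het_scale = 1, gamma_internal = 1,
    kon, KD,
    setNames(dr$kasc, paste0("kasc_", dn)),
    setNames(rep(0.10, length(dn)), paste0("kdis_", dn)),
    setNames(dr$kint, paste0("kint_", dn)),
    setNames(rep(0.03, length(dn)), paste0("krec_", dn)),
    setNames(dr$kx, paste0("kxdeg_", dn)),
    setNames(wM, paste0("wMAPK_", dn)),
    setNames(wP, paste0("wPI3K_", dn)),
    downstreamDefaults()
  )
  if ("BTC" %in% lig) {
    p <- c(p, "mult_BTC_EGFR:EGFR" = 3.0, "mult_BTC_EGFR:HER2" = 0.3)
  }
  p
}

requiredKineticNames <- function(spec) {
  names(defaultKinetics(spec))
}

validateKinetics <- function(spec, params) {
  need <- requiredKineticNames(spec)
  miss <- setdiff(need, names(params))
  if (length(miss))
    ltStop("config", paste("missing kinetic parameter(s):",
                           paste(miss, collapse = ", ")))
  strictPos <- grepl("^(kon_|KD_|kdis_|kint_|ka_|kd_)|_total$",
                     names(params))
  bad <- names(params)[strictPos & !(is.finite(params) & params > 0)]
  if (length(bad))
    ltStop("config", paste("rate parameter(s) must be > 0:",
                           paste(bad, collapse = ", ")))
  # association rates may be 0 (a dimer that never forms) and turnover
  # rates may be switched off for conservation analyses
  nonNeg <- grepl(paste0("^(kasc_|krec_|kxdeg_|wMAPK_|wPI3K_|kfb_|mult_)",
                         "|^f_spont$|^het_scale$|^kdeg_R$"),
                  names(params))
  bad <- names(params)[nonNeg & !(is.finite(params) & params >= 0)]
  if (length(bad))
    ltStop("config", paste("parameter(s) must be >= 0:",
                           paste(bad, collapse = ", ")))
  g <- params["gamma_internal"]
  if (!is.finite(g) || g < 0 || g > 1)
    ltStop("config", "gamma_internal must lie in [0, 1]")
  dn <- dimerNames(spec)
  wOff <- !spec@dimers$signaling
  if (any(wOff)) {
    wz <- c(params[paste0("wMAPK_", dn[wOff])],
            params[paste0("wPI3K_", dn[wOff])])
    if (any(wz != 0))
      ltStop("config",
             "pathway weights of non-signaling dimers must be 0")
  }
  invisible(TRUE)
}
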