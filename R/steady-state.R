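# Ligand-free basal steady state.
#
# With all doses zero the bound-monomer pools vanish and the receptor
# subsystem closes analytically: spontaneous dimer formation fluxes are
# quadratic in the (known, measured) free-receptor levels, the two dimer
# pools follow linearly, and the per-receptor synthesis rates are solved
# from the free-monomer balance so that the measured surface expression
# IS the basal level.  The two downstream feedback loops each reduce to a
# scalar monotone fixed point solved by bracketed root finding.

cellContext <- function(x, line = NULL) {
  if (is(x, "CellLinePanel")) {
    df <- x@data
    if (!is.null(line)) df <- df[df$cell_line == line, , drop = FALSE]
    if (nrow(df) != 1L)
      ltStop("schema", "context must resolve to exactly one cell line")
    list(name = df$cell_line,
         receptors = unlist(df[1, RECEPTORS]),
         kras_mutant = df$kras_mutant, pik3ca_mutant = df$pik3ca_mutant)
  } else if (is.list(x)) {
    stopifnot(!is.null(x$receptors))
    x$receptors <- x$receptors[RECEPTORS]
    x$name <- x$name %||% "cell_line"
    x$kras_mutant <- x$kras_mutant %||% FALSE
    x$pik3ca_mutant <- x$pik3ca_mutant %||% FALSE
    x
  } else ltStop("schema", "context must be a CellLinePanel or a list")
}

solveFixedPoint <- function(f, upper) {
  if (f(0) <= 0) return(0)
  root <- uniroot(f, c(0, upper), tol = 1e-13 * max(1, upper))$root
  root
}

#' Basal steady state of a cell line
#'
#' Computes the ligand-free steady state analytically: basal dimer and
#' downstream phospho-levels follow from the measured receptor surface
#' expression via spontaneous dimerization, and receptor synthesis rates
#' are chosen so the expression levels are reproduced exactly.  A
#' long-horizon pre-equilibration fallback covers any case where the
#' residual check fails.
#'
#' @param model an [RTKModel-class].
#' @param context a [CellLinePanel-class] row (give `line` if the panel
#'   has several) or a list with elements `name` and `receptors` (named
#'   numeric, molecules/cell).
#' @param line optional cell line name selecting a panel row.
#' @param tolSS residual tolerance, max |f(x0)| normalized per component
#'   by max(1, |x0|).
#' @return list with elements `x0` (named state vector), `synthesis`
#'   (named per-receptor synthesis rates, molecules/cell/min),
#'   `residual`, and `cellLine`.
#' @export
steadyState <- function(model, context, line = NULL, tolSS = 1e-8) {
  ctx <- cellContext(context, line)
  R <- ctx$receptors
  if (any(!is.finite(R)) || any(R < 0))
    ltStop("config", "receptor expression must be finite and >= 0")
  p <- model@params
  st <- model@structure
  d <- st$dimers

  kasc <- unname(p[paste0("kasc_", d$name)]) * p[["f_spont"]] *
    ifelse(d$homo, 1, p[["het_scale"]])
  Fd <- kasc * R[d$recA] * R[d$recB]
  kdis <- unname(p[paste0("kdis_", d$name)])
  kint <- unname(p[paste0("kint_", d$name)])
  krec <- unname(p[paste0("krec_", d$name)])
  kx <- unname(p[paste0("kxdeg_", d$name)])
  Ds <- Fd / (kdis + kint)
  Di <- kint * Ds / (krec + kx)
  # per-receptor net loss into the dimer compartment
  net <- Fd - kdis * Ds - krec * Di
  syn <- p[["kdeg_R"]] * unname(R)
  for (k in seq_len(nrow(d))) {
    m <- ifelse(d$homo[k], 2, 1)
    syn[d$recAi[k] + 1L] <- syn[d$recAi[k] + 1L] + m * net[k]
    if (!d$homo[k])
      syn[d$recBi[k] + 1L] <- syn[d$recBi[k] + 1L] + net[k]
  }

  gam <- p[["gamma_internal"]]
  act <- Ds + gam * Di
  CM <- sum(unname(p[paste0("wMAPK_", d$name)]) * act)
  CP <- sum(unname(p[paste0("wPI3K_", d$name)]) * act)

  totM <- p[["MEK_total"]]; totE <- p[["ERK_total"]]
  totA <- p[["AKT_total"]]; totK <- p[["S6K1_total"]]
  totS <- p[["S6_total"]]
  pMEKof <- function(e) {
    a <- p[["ka_MEK"]] * CM / (1 + p[["kfb_ERK"]] * e)
    totM * a / (a + p[["kd_MEK"]])
  }
  pERK <- solveFixedPoint(function(e) {
    b <- p[["ka_ERK"]] * pMEKof(e)
    totE * b / (b + p[["kd_ERK"]]) - e
  }, totE)
  pMEK <- pMEKof(pERK)
  pAKTof <- function(s) {
    a <- p[["ka_AKT"]] * CP / (1 + p[["kfb_S6K1"]] * s)
    totA * a / (a + p[["kd_AKT"]])
  }
  pS6K1 <- solveFixedPoint(function(s) {
    q <- p[["ka_S6K1_ERK"]] * pERK + p[["ka_S6K1_AKT"]] * pAKTof(s)
    totK * q / (q + p[["kd_S6K1"]]) - s
  }, totK)
  pAKT <- pAKTof(pS6K1)
  r6 <- p[["ka_S6"]] * pS6K1
  pS6 <- totS * r6 / (r6 + p[["kd_S6"]])

  x0 <- numeric(st$nState)
  names(x0) <- st$stateNames
  x0[st$iR + 1L] <- unname(R)
  x0[d$iDs + 1L] <- Ds
  x0[d$iDi + 1L] <- Di
  x0[st$downIdx + 1L] <- c(pMEK, pERK, pAKT, pS6K1, pS6)

  ptr <- packParms(model, syn)
  resid <- ssResidual(ptr, x0)
  if (resid > tolSS) {
    # pre-equilibration fallback: relax by long-horizon integration
    activateModelCpp(ptr)
    out <- deSolve::lsoda(
      y = x0, times = c(0, 5e4, 1e5),
      func = "lt_derivs", dllname = "ligandtree", initfunc = NULL,
    parms = NULL,
      rtol = 1e-10, atol = 1e-10, maxsteps = 1e5)
    x0 <- out[nrow(out), -1]
    names(x0) <- st$stateNames
    resid <- ssResidual(ptr, x0)
    if (resid > tolSS)
      ltStop("numerical", sprintf(
        "steady state did not converge: residual %.3e > %.1e",
        resid, tolSS))
  }
  list(x0 = x0, synthesis = setNames(syn, st$receptors),
       residual = resid, cellLine = ctx$name)
}

ssResidual <- function(ptr, x0) {
  f <- rhsCpp(ptr, 0, unname(x0))
  max(abs(f) / pmax(1, abs(x0)))
}
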