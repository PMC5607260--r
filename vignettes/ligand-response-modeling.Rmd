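---
title: "Mechanistic signaling features and bagged decision trees for ligand-dependent proliferation"
author: "ligandtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic signaling features and bagged decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandtree)
```

# The problem

Growth-factor (ligand) addiction is a candidate driver of tumor growth
alongside oncogene addiction: a tumor cell that expresses the right
receptor complement proliferates when EGF, heregulin (HRG), HGF or
IGF-1 is present in its microenvironment.  Receptor surface levels
alone, however, correlate poorly with the proliferative response,
because the response is shaped by receptor *interactions* — which homo-
and heterodimers form at a given receptor stoichiometry, how they
traffic, and how the MAPK and PI3K cascades integrate their input.

`ligandtree` implements a two-stage pipeline:

1. a mechanistic ODE model of ErbB-family, Met and IGF-1R signaling in
   which **all kinetic parameters are shared across cell lines** and
   only the five receptor surface expression levels are cell-line
   specific, and
2. **bagged decision trees (BDTs)** with a signal-to-noise split gain
   that map simulated signaling features (areas under the curve of
   phosphorylated dimers and downstream kinases) plus mutation status
   to the observed proliferation phenotype.

Every pipeline stage can be exercised on synthetic data with known
ground truth; the packaged cell-line table (58 lines with KRAS/PIK3CA
annotations and absolute receptor surface levels) provides realistic
receptor stoichiometries.

# The signaling model

## Network

Five receptors (EGFR, HER2, ErbB3, Met, IGF-1R) bind their ligands
(EGF and BTC for EGFR, HRG for ErbB3, HGF for Met, IGF-1 for IGF-1R;
HER2 has no ligand) and pair into ten dimers: the five homodimers plus
EGFR:HER2, EGFR:ErbB3, EGFR:Met, HER2:ErbB3 and ErbB3:Met.  The ErbB3
homodimer forms but cannot trans-phosphorylate — ErbB3 lacks a
functional kinase, so at least one partner with kinase activity is
needed — and therefore carries zero weight into the cascades.  Two
further variants exist: `with_igf1r_heterodimers` adds EGFR:IGF1R and
HER2:IGF1R (removing them changes nothing when their association rates
are zero, which the test suite verifies by trajectory equivalence), and
`no_heterodimers` keeps only the five homodimers with ErbB3 allowed to
signal — the reduced comparison network for the likelihood-ratio test.

## State inventory

The inventory is the smallest one supporting every arrow of the
network: per receptor a free surface monomer; per (ligand, receptor)
pair a ligand-bound surface monomer; per dimer a phosphorylated surface
pool and an internalized pool; and active fractions of MEK, ERK, AKT,
S6K1 and S6 with conserved totals.  The 10-dimer network has
`r nStates(buildModel())` states (5 free + 5 bound monomers, 2 × 10
dimer pools, 5 downstream).  Deliberate simplifications:

* **Ligand is a constant bath input**, not a state: the assays this
  emulates apply ligand in bulk medium, so depletion is negligible.
* **Trans-phosphorylation is instantaneous on dimerization** — dimer
  formation directly yields the phospho-dimer (except non-signaling
  dimers).  The intermediate unphosphorylated dimer is not resolvable
  from phospho-site data.
* **Internalized dimers keep signaling** by default
  (`gamma_internal = 1`, exposed as a parameter in `[0, 1]`), since
  endosomal RTK signaling is well documented and phospho-assays do not
  separate the pools.

Dimer formation is mass action over every pair of monomer pools of the
two partner receptors; pairs of two unliganded monomers use the
spontaneous factor `f_spont` (default 0.02), pairs involving at least
one ligand-bound monomer dimerize at the full rate, and per-ligand
multipliers let BTC favor the EGFR homodimer (x3) while disfavoring
EGFR:HER2 (x0.3) relative to EGF.  Dissociation returns free monomers;
internalized dimers are either recycled to free surface monomers or
degraded.  The cascades are driven by the weighted sums
$C_\mathrm{MAPK} = \sum_D w_{D,\mathrm{MAPK}}\,(D_s + \gamma D_i)$ and
$C_\mathrm{PI3K}$ analogously, with two negative feedbacks as
multiplicative $1/(1 + k\,[\cdot])$ terms: pERK inhibits the MAPK input
(SOS-like) and pS6K1 the PI3K input (IRS-like).  Both cascades converge
on S6K1 and then S6.

## Units

Receptor and downstream abundances are molecules/cell (the packaged
table prints thousands/cell and is converted on load); ligand doses are
nM; time is minutes.  Bimolecular dimerization rates are per
(molecules/cell) per minute — no volume conversion is applied anywhere,
the rate constants absorb the unit choice.

## Parameter defaults

All defaults are literature-plausible magnitudes, not fits: on-rates of
0.06 /nM/min (about 1e6 /M/s), dissociation constants of 0.5–2 nM,
receptor half-lives of hours (`kdeg_R` 0.005 /min), dimer
internalization on the minutes scale and downstream phospho-turnover of
0.2–0.3 /min.  Two asymmetries are chosen so the model reproduces
qualitative behaviors the panel shows:

* trafficking: homodimer pools turn over slowly while EGFR:HER2
  internalizes and degrades fast.  An EGFR-high line then sustains
  receptor phosphorylation over 240 min (large reservoir, slow loss)
  while a line whose scarce EGFR is consumed by heterodimers peaks
  early and decays — the sustained-versus-transient contrast between
  EGFR-high and EGFR-low lines;
* association: HER2 is the preferred partner (EGFR:HER2 and HER2:ErbB3
  at 8e-7 and 4e-7 versus 0.5–2e-7 elsewhere).  Under EGF+HRG
  co-stimulation, ligand-bound EGFR then sequesters free HER2, reduces
  HER2:ErbB3 formation, and lowers phospho-ErbB3 relative to HRG alone
  in EGFR-high contexts — receptor competition producing a non-obvious
  response to a ligand mixture.

Mutation flags never touch the ODEs; they are classifier inputs only.

## Basal steady state

With all doses zero, the bound pools vanish and the receptor subsystem
closes analytically: spontaneous formation fluxes are quadratic in the
(measured, hence known) free receptor levels, both dimer pools follow
linearly, and the per-receptor synthesis rates are solved from the
free-monomer balance so that the measured surface expression *is* the
basal state.  The two feedback loops each reduce to a scalar monotone
fixed point solved by bracketed root finding to near machine precision;
the residual contract is max |f(x0)| <= 1e-8 (normalized per component
by max(1, |x0|)), and a long-horizon pre-equilibration fallback exists
for parameter regions where the analytic construction might fall short.
Because basal dimer and downstream levels derive from the receptor
levels, expression changes propagate through the whole resting state —
which is what makes receptor expression alone an informative cell-line
fingerprint.

## Integration

The right-hand side is compiled C++ called natively by `deSolve::lsoda`
(relative/absolute tolerances 1e-8/1e-10).  Under these tolerances a
ligand-free simulation of every packaged cell line stays within 1e-6
relative of its computed steady state over 240 min, and per-receptor
copy totals are conserved to better than 1e-9 relative when synthesis
and turnover are switched off.

# Calibration

Measurements link to the model through per-observable scale and offset
parameters with Gaussian errors, achieved here via log transformation:
synthetic time courses carry multiplicative log-normal noise (default
sigma 0.15, a typical immunoassay CV) and residuals are formed on the
log scale.  The default observation map adds a background offset of 1
molecule/cell, which keeps the log likelihood finite and continuous
when a phospho-pool is exactly zero (as in reduced variants).  The
chi-square is the sum of squared sigma-weighted residuals, and fitting
is multi-start trust-region least squares (`minpack.lm::nls.lm`) in
log10 parameter space — by default 50 starts drawn log-uniform within
±2 decades of the nominal values, seeded and reproducible.

The calibration scheme mirrors the shared-kinetics design: all rate
constants global, only receptor expression per line.  On synthetic time
courses from two lines with receptor levels spanning the panel's range
(design: four ligands at 0.625 and 10 nM, 12-point grid from 0 to
240 min, default noise), 20 starts recover every receptor expression to
within a few percent (the acceptance surface requires 20%).

## The heterodimer likelihood-ratio test

Comparing the full network against `no_heterodimers` is a *boundary*
test: the null fixes association rates at the edge of the parameter
space, where the usual chi-square reference of Wilks' theorem fails
badly (rejection far below nominal).  `lrtReduced()` therefore offers
the standard one-parameter chi-bar-square mixture
$p = \tfrac12 P(\chi^2_1 > \mathrm{stat})$ alongside the plain
chi-square tail.  The calibration harness
(`lrtHeterodimerCalibration()`) generates data without heterodimers,
fits a single global heterodimer-association scale (log10, seeded from
a coarse deterministic profile because the log-scale likelihood is flat
near the lower edge), and observes the expected behavior: about half
the replicates see zero improvement, the nonzero statistics follow
chi-square(1), and the rejection rate sits at the nominal 5%.  With
heterodimers present in the generating model the reduced fit collapses
and p-values vanish — the power direction.

# Features and phenotype

`featureTable()` simulates each (line, ligand) pair at the screen doses
(5 nM EGF, 5 nM HRG, 1 nM HGF, 50 nM IGF-1) and integrates the total
phospho-level of the nine signaling dimers plus pAKT, pERK and pS6 by
the trapezoidal rule over 0–240 min — the 12-feature set.  AUCs are raw
(not baseline-subtracted; a flag flips this), and fold-change and
quasi-steady-state extras are available.  Features are log10
transformed before classification because receptor inputs span orders
of magnitude; threshold splits are order-preserving, so this is
cosmetic for single-feature splits.

Responder calling follows the screen's rule exactly: a (line,
treatment) is a responder iff its day-3 viability exceeds the reference
by more than 20% AND the quadruplicates differ at alpha = 0.05 by a
two-sided Wilcoxon rank-sum test, computed by exact enumeration for
combined n <= 12 (mid-ranks under ties).  Two degenerate facts matter
and are tested: with quadruplicates the smallest attainable p is
2/70 ≈ 0.029, so responder calls require near-complete separation; with
triplicates the minimum is 2/20 = 0.1 and no call could ever clear
alpha = 0.05.  The effect ratio uses means (option for medians); the
mirrored rule (>= 20% below reference) serves inhibition calls, and a
threshold sweep utility recomputes calls across 10–30%.

# Bagged decision trees

Trees split greedily on the feature and threshold maximizing the gain
in summed squared significance
$\sum_c S_c^2/(S_c+B_c) - S_p^2/(S_p+B_p)$, with S/B the
responder/non-responder counts.  This is the squared version of the
S/√(S+B) significance familiar from counting experiments; squaring
makes the gain additive and non-negative (zero iff the split is
uninformative).  For binary labels this quantity is proportional to the
Gini impurity decrease, so the `"gini"` criterion selects identical
splits and differs only in the gain scale — a coincidence worth knowing
when comparing importances.  Thresholds sit at the largest left-child
training value with `<=` comparison, which makes predictions *exactly*
invariant under strictly monotone transforms of any feature applied to
training and test data alike (midpoint thresholds would break this for
test points between straddling training values).  Ties break to the
lowest feature index, then the lowest threshold, so training is
deterministic given the bootstrap draw.

Defaults: 200 trees, bootstrap fraction 1.0 with replacement, depth
limit 4, minimum leaf 3 — sized for a 58-line panel.  Importance is the
mean split gain per feature over all trees, normalized to a maximum of
1 by default.

`evaluateSplits()` implements the evaluation scheme: cell lines (not
rows) are split 500 times into 70% training / 30% testing, the ensemble
is trained on all training rows across ligands, and the fraction of
true predictions is scored on held-out lines for the target ligand (or
all ligands combined, from which IGF-1 is excluded by default — its
responders are too rare for stable training).  The random control
replaces labels by fair coin flips and lands at 50% accuracy with the
binomial spread expected from the test-set size; `compareToControl()`
is a one-sided paired Wilcoxon signed-rank test across repetitions.

# Synthetic data and what passing tests mean

The generators define the study conditions:

* `makeCellLines()`: receptor counts log-uniform over 3e3–5.5e6
  molecules/cell (the packaged panel's span); mutation frequencies
  computed from the panel at run time.
* `makeTimecourses()`: the assay design (four doses 0.156–10 nM per
  ligand, pairwise co-stimulations at 2.5 nM, 12 time points 0–240
  min), log-normal noise sigma 0.15.
* `makeViability()`: quadruplicates with 5% CV, day-3 responder effect
  +30% over control, 10% label noise — so ~90% label agreement is the
  ceiling any classifier can reach.
* planted rule: responder iff pS6 AUC above its panel median — a
  depth-1 rule on the true features (a depth-2 alternative exists).
  pS6 is the natural choice: both cascades converge on it.
* `makeCohort()`: log-normal receptor TPM, planted responders defined
  by the same pS6-AUC rule after the cohort mean-normalization the
  prediction path applies, ligand genes shifted +1 log2 in responders.

Synthetic data share the model's structural assumptions, so passing
tests demonstrate that the machinery is correct and internally
consistent — parameter recovery, test calibration, planted-rule
recovery — not that the model is true of any real cell line.  Plate
effects, batch structure, autocrine signaling and mutation-dependent
kinetics are deliberately absent.

# Cohort prediction

Cohort mRNA and the panel's qFACS counts live on different scales, so
expressions are normalized to their per-gene cohort means and anchored
to the panel's mean surface counts (the anchor choice is this package's
own; a fitted log10-log10 linear map between mRNA and surface counts is
the alternative route, also used to impute the panel's unprinted IGF1R
column if desired — the default imputation is a flagged constant of
30e3/cell, the scale of the printed ErbB3/Met columns).  Each sample is
then simulated like a cell line (mutations wild-type when the cohort
has none), the ensemble votes, and `ligandAssociation()` compares log2
ligand-gene expression between predicted responders and non-responders
by a two-sample t-test.

# Numerical choices, reproducibility, limitations

* Steady states: bracketed scalar root finding at tolerance ~1e-13 of
  the totals; residual contract 1e-8; integrator 1e-8/1e-10.
* All stochastic stages take integer seeds and are bit-reproducible;
  `runPipeline()` derives stage seeds from one master seed and stamps
  every artifact with the configuration hash.
* Problem sizes used by the shipped checks: 58-line panel for features
  and splits (500 repetitions), 2 lines for parameter recovery (20
  starts), 200 replicates for LRT calibration on a 1-line, 2-condition
  design, 400-sample cohorts.
* Known limitations: the state inventory is a minimal reading of the
  network (other implementations of the same biology may resolve more
  intermediate species and count more states); no antibody
  pharmacology, no receptor-mutant
  kinetics, no JAK-STAT or other pathways; `no_heterodimers` boundary
  testing is exact only for the single-scale parameterization (df = 1);
  the signal-to-noise/Gini equivalence means the two criteria are not
  independent checks of each other.
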