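// Right-hand side of the receptor-dimerization / trafficking / MAPK-PI3K
// cascade ODE system.  The network structure (state indices, monomer-pair
// list, dimer index arrays) is assembled in R and packed once into a C++
// struct; the integrator then evaluates the RHS without any R-level lookup.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct ModelP {
  int nState, nR, nB, nPairs, nD;
  std::vector<int> iR;                   // free surface receptor states
  std::vector<int> bRec, iB;             // ligand-bound monomers
  std::vector<int> pI, pJ, pD, pSame;    // dimer-formation pair list
  std::vector<int> iDs, iDi, dRecA, dRecB, dHomo;
  int iMEK, iERK, iAKT, iS6K, iS6;
  std::vector<double> syn, kdegR;
  std::vector<double> konu, koff;        // konu = kon * ligand dose
  std::vector<double> pK;                // effective association rate per pair
  std::vector<double> kd, ki, kr, kx, wM, wP;
  double totM, totE, totA, totK, totS;
  double kaMEK, kaERK, kaAKT, kaKE, kaKA, kaS6;
  double kdM, kdE, kdA, kdK, kdS;
  double kfbE, kfbS, gamma;
};

static std::vector<int> ivec(List P, const char* nm) {
  IntegerVector v = P[nm];
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> dvec(List P, const char* nm) {
  NumericVector v = P[nm];
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
SEXP packModelCpp(List P) {
  ModelP* m = new ModelP();
  m->nState = as<int>(P["nState"]);
  m->nR = as<int>(P["nR"]);
  m->nB = as<int>(P["nB"]);
  m->nPairs = as<int>(P["nPairs"]);
  m->nD = as<int>(P["nD"]);
  m->iR = ivec(P, "iR");
  m->bRec = ivec(P, "bRec");
  m->iB = ivec(P, "iB");
  m->pI = ivec(P, "pI");
  m->pJ = ivec(P, "pJ");
  m->pD = ivec(P, "pD");
  m->pSame = ivec(P, "pSame");
  m->iDs = ivec(P, "iDs");
  m->iDi = ivec(P, "iDi");
  m->dRecA = ivec(P, "dRecA");
  m->dRecB = ivec(P, "dRecB");
  m->dHomo = ivec(P, "dHomo");
  m->iMEK = as<int>(P["iMEK"]);
  m->iERK = as<int>(P["iERK"]);
  m->iAKT = as<int>(P["iAKT"]);
  m->iS6K = as<int>(P["iS6K"]);
  m->iS6  = as<int>(P["iS6"]);
  m->syn = dvec(P, "syn");
  m->kdegR = dvec(P, "kdegR");
  m->konu = dvec(P, "konu");
  m->koff = dvec(P, "koff");
  m->pK = dvec(P, "pK");
  m->kd = dvec(P, "kd");
  m->ki = dvec(P, "ki");
  m->kr = dvec(P, "kr");
  m->kx = dvec(P, "kx");
  m->wM = dvec(P, "wM");
  m->wP = dvec(P, "wP");
  NumericVector tot = P["tot"];
  m->totM = tot[0]; m->totE = tot[1]; m->totA = tot[2];
  m->totK = tot[3]; m->totS = tot[4];
  NumericVector ka = P["ka"];
  m->kaMEK = ka[0]; m->kaERK = ka[1]; m->kaAKT = ka[2];
  m->kaKE = ka[3]; m->kaKA = ka[4]; m->kaS6 = ka[5];
  NumericVector kdd = P["kdd"];
  m->kdM = kdd[0]; m->kdE = kdd[1]; m->kdA = kdd[2];
  m->kdK = kdd[3]; m->kdS = kdd[4];
  m->kfbE = as<double>(P["kfbE"]);
  m->kfbS = as<double>(P["kfbS"]);
  m->gamma = as<double>(P["gamma"]);
  XPtr<ModelP> ptr(m, true);
  return ptr;
}

static inline double pos(double v) { return v > 0.0 ? v : 0.0; }

static void computeRhs(const ModelP* m, const double* x, double* dx) {
  const int n = m->nState;
  for (int i = 0; i < n; ++i) dx[i] = 0.0;

  // receptor synthesis and turnover
  for (int r = 0; r < m->nR; ++r) {
    int i = m->iR[r];
    dx[i] += m->syn[r] - m->kdegR[r] * pos(x[i]);
  }
  // ligand binding / unbinding (ligand is a constant bath input)
  for (int b = 0; b < m->nB; ++b) {
    int ir = m->iR[m->bRec[b]], ib = m->iB[b];
    double on = m->konu[b] * pos(x[ir]);
    double off = m->koff[b] * pos(x[ib]);
    dx[ir] += off - on;
    dx[ib] += on - off - m->kdegR[m->bRec[b]] * pos(x[ib]);
  }
  // dimer formation from monomer-pool pairs
  for (int p = 0; p < m->nPairs; ++p) {
    int i = m->pI[p], j = m->pJ[p], d = m->pD[p];
    double f = m->pK[p] * pos(x[i]) * pos(x[j]);
    if (m->pSame[p]) {
      dx[i] -= 2.0 * f;
    } else {
      dx[i] -= f;
      dx[j] -= f;
    }
    dx[m->iDs[d]] += f;
  }
  // dimer dissociation, trafficking, and return of monomers
  double CM = 0.0, CP = 0.0;
  for (int d = 0; d < m->nD; ++d) {
    double ds = pos(x[m->iDs[d]]), di = pos(x[m->iDi[d]]);
    dx[m->iDs[d]] += -(m->kd[d] + m->ki[d]) * ds;
    dx[m->iDi[d]] += m->ki[d] * ds - (m->kr[d] + m->kx[d]) * di;
    double back = m->kd[d] * ds + m->kr[d] * di;
    if (m->dHomo[d]) {
      dx[m->iR[m->dRecA[d]]] += 2.0 * back;
    } else {
      dx[m->iR[m->dRecA[d]]] += back;
      dx[m->iR[m->dRecB[d]]] += back;
    }
    double act = ds + m->gamma * di;
    CM += m->wM[d] * act;
    CP += m->wP[d] * act;
  }
  // downstream cascades with negative feedback on the pathway inputs
  double pMEK = pos(x[m->iMEK]), pERK = pos(x[m->iERK]);
  double pAKT = pos(x[m->iAKT]), pS6K = pos(x[m->iS6K]);
  double pS6 = pos(x[m->iS6]);
  double CMeff = CM / (1.0 + m->kfbE * pERK);
  double CPeff = CP / (1.0 + m->kfbS * pS6K);
  dx[m->iMEK] = m->kaMEK * CMeff * (m->totM - pMEK) - m->kdM * pMEK;
  dx[m->iERK] = m->kaERK * pMEK * (m->totE - pERK) - m->kdE * pERK;
  dx[m->iAKT] = m->kaAKT * CPeff * (m->totA - pAKT) - m->kdA * pAKT;
  dx[m->iS6K] = (m->kaKE * pERK + m->kaKA * pAKT) * (m->totK - pS6K) -
                m->kdK * pS6K;
  dx[m->iS6]  = m->kaS6 * pS6K * (m->totS - pS6) - m->kdS * pS6;
}

// [[Rcpp::export]]
NumericVector rhsCpp(SEXP xp, double t, NumericVector x) {
  XPtr<ModelP> m(xp);
  NumericVector dx(m->nState);
  computeRhs(m.get(), x.begin(), dx.begin());
  return dx;
}

// The integrator calls the RHS through this native entry point, which
// avoids an R round trip per evaluation.  The model to evaluate is
// selected beforehand with activateModelCpp().
static ModelP* g_active = 0;

// [[Rcpp::export]]
void activateModelCpp(SEXP xp) {
  XPtr<ModelP> p(xp);
  g_active = p.get();
}

extern "C" void lt_derivs(int* neq, double* t, double* y, double* ydot,
                          double* yout, int* ip) {
  computeRhs(g_active, y, ydot);
}

// Pathway input terms (weighted sums of active dimers), exposed for the
// unit-level check that non-signaling dimers contribute zero flux.
// [[Rcpp::export]]
NumericVector cascadeInputCpp(SEXP xp, NumericVector x) {
  XPtr<ModelP> m(xp);
  double CM = 0.0, CP = 0.0;
  for (int d = 0; d < m->nD; ++d) {
    double act = pos(x[m->iDs[d]]) + m->gamma * pos(x[m->iDi[d]]);
    CM += m->wM[d] * act;
    CP += m->wP[d] * act;
  }
  return NumericVector::create(_["MAPK"] = CM, _["PI3K"] = CP);
}
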