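// Greedy binary decision tree with a signal-to-noise split gain.
// The gain of a candidate split is the increase in the summed squared
// significance S^2/(S+B) over the child nodes relative to the parent
// (S = responder count, B = non-responder count); for binary labels this
// is proportional to the Gini impurity decrease, which is offered as the
// alternative criterion (it differs only in the reported gain scale).
// Thresholds sit AT the largest left-child value with `<=` comparison so
// that predictions are exactly invariant under strictly monotone feature
// transforms applied to training and test data alike.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature, left, right, nNode, nSig;
  std::vector<double> threshold, gain, frac;
};

static double nodeScore(double S, double n) {
  return n > 0.0 ? S * S / n : 0.0;
}

static int growNode(const NumericMatrix& X, const IntegerVector& y,
                    std::vector<int>& rows, int lo, int hi, int depth,
                    int depthLimit, int minLeaf, int criterion, int nRoot,
                    TreeBuf& T) {
  const int n = hi - lo;
  int S = 0;
  for (int k = lo; k < hi; ++k) S += y[rows[k]];
  const int id = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(NA_REAL);
  T.gain.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.nNode.push_back(n);
  T.nSig.push_back(S);
  T.frac.push_back(n > 0 ? (double)S / n : 0.0);

  if (depth >= depthLimit || S == 0 || S == n || n < 2 * minLeaf) return id;

  const int p = X.ncol();
  const int nAll = X.nrow();
  const double* xp = X.begin();
  double bestGain = 0.0, bestThr = 0.0;
  int bestF = -1;
  std::vector<std::pair<double, int> > vals(n);
  const double parent = nodeScore((double)S, (double)n);

  for (int f = 0; f < p; ++f) {
    const double* col = xp + (size_t)f * nAll;
    for (int k = 0; k < n; ++k) {
      int r = rows[lo + k];
      vals[k] = std::make_pair(col[r], y[r]);
    }
    std::sort(vals.begin(), vals.end());
    int Sl = 0;
    for (int k = 1; k < n; ++k) {
      Sl += vals[k - 1].second;
      if (vals[k - 1].first >= vals[k].first) continue;  // tied values
      int nl = k, nr = n - k;
      if (nl < minLeaf || nr < minLeaf) continue;
      double g = nodeScore((double)Sl, (double)nl) +
                 nodeScore((double)(S - Sl), (double)nr) - parent;
      if (g > bestGain + 1e-12) {
        bestGain = g;
        bestF = f;
        bestThr = vals[k - 1].first;
      }
    }
  }
  if (bestF < 0 || bestGain <= 1e-12) return id;

  // partition rows in place: left = x <= thr
  const double* bcol = xp + (size_t)bestF * nAll;
  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int k = lo; k < hi; ++k) {
    if (bcol[rows[k]] <= bestThr) lrows.push_back(rows[k]);
    else rrows.push_back(rows[k]);
  }
  for (size_t k = 0; k < lrows.size(); ++k) rows[lo + k] = lrows[k];
  for (size_t k = 0; k < rrows.size(); ++k) rows[lo + lrows.size() + k] = rrows[k];
  int mid = lo + (int)lrows.size();

  T.feature[id] = bestF;
  T.threshold[id] = bestThr;
  T.gain[id] = (criterion == 1) ? bestGain / nRoot : bestGain;
  int lid = growNode(X, y, rows, lo, mid, depth + 1, depthLimit, minLeaf,
                     criterion, nRoot, T);
  int rid = growNode(X, y, rows, mid, hi, depth + 1, depthLimit, minLeaf,
                     criterion, nRoot, T);
  T.left[id] = lid;
  T.right[id] = rid;
  return id;
}

// [[Rcpp::export]]
List growTreeCpp(NumericMatrix X, IntegerVector y, IntegerVector rows,
                 int depthLimit, int minLeaf, int criterion) {
  std::vector<int> rw(rows.begin(), rows.end());
  TreeBuf T;
  growNode(X, y, rw, 0, (int)rw.size(), 0, depthLimit, minLeaf, criterion,
           (int)rw.size(), T);
  return List::create(
      _["feature"] = wrap(T.feature), _["threshold"] = wrap(T.threshold),
      _["gain"] = wrap(T.gain), _["left"] = wrap(T.left),
      _["right"] = wrap(T.right), _["n"] = wrap(T.nNode),
      _["n_sig"] = wrap(T.nSig), _["frac"] = wrap(T.frac));
}

// [[Rcpp::export]]
NumericVector predictTreeCpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], frac = tree["frac"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = frac[node];
  }
  return out;
}
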