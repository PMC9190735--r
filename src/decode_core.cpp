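// Time-resolved pairwise linear SVM decoding loops.
//
// The classifier is a soft-margin linear SVM (hinge loss, fixed cost)
// trained by sequential minimal optimization on the dual. Training sets
// here are tiny (a handful of super-trials per class), so a plain SMO
// with maximal-|E_i - E_j| working-pair selection converges in a few
// passes; the convex dual has a unique optimum in w, which is what the
// predictions depend on.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LinSVM {
  vec w;
  double b;
};

LinSVM smoTrain(const mat& X, const vec& y, double C,
                double eps = 1e-9, int maxIter = 100000) {
  const int n = X.n_rows;
  mat K = X * X.t();
  vec alpha(n, fill::zeros);
  // dual gradient of 0.5 a'Qa - e'a with Q_ij = y_i y_j K_ij
  vec G(n, fill::value(-1.0));

  // maximal-violating-pair working-set selection
  for (int iter = 0; iter < maxIter; ++iter) {
    int i = -1, j = -1;
    double up = -datum::inf, low = datum::inf;
    for (int t = 0; t < n; ++t) {
      bool inUp = (y(t) > 0 && alpha(t) < C) || (y(t) < 0 && alpha(t) > 0);
      bool inLow = (y(t) > 0 && alpha(t) > 0) || (y(t) < 0 && alpha(t) < C);
      double v = -y(t) * G(t);
      if (inUp && v > up) { up = v; i = t; }
      if (inLow && v < low) { low = v; j = t; }
    }
    if (i < 0 || j < 0 || up - low < eps) break;

    double aiOld = alpha(i), ajOld = alpha(j);
    double quad = std::max(K(i, i) + K(j, j) - 2.0 * K(i, j), 1e-12);
    double delta = (up - low) / quad;
    // unclipped optimum along the feasible direction, then projection
    // onto the box while keeping y'alpha constant
    double sumConst = y(i) * aiOld + y(j) * ajOld;
    double aiNew = aiOld + y(i) * delta;
    aiNew = std::min(C, std::max(0.0, aiNew));
    double ajNew = y(j) * (sumConst - y(i) * aiNew);
    if (ajNew < 0.0) { ajNew = 0.0; aiNew = y(i) * sumConst; }
    if (ajNew > C) { ajNew = C; aiNew = y(i) * (sumConst - y(j) * C); }
    aiNew = std::min(C, std::max(0.0, aiNew));
    double dAi = aiNew - aiOld, dAj = ajNew - ajOld;
    if (std::abs(dAi) < 1e-15 && std::abs(dAj) < 1e-15) break;
    alpha(i) = aiNew;
    alpha(j) = ajNew;
    G += (y(i) * dAi) * (y % K.col(i)) + (y(j) * dAj) * (y % K.col(j));
  }

  LinSVM m;
  m.w = X.t() * (alpha % y);
  // offset from the KKT interval of the final alphas
  vec f = X * m.w;
  double lo = -datum::inf, hi = datum::inf;
  const double bnd = 1e-9;
  for (int t = 0; t < n; ++t) {
    if (y(t) > 0) {
      if (alpha(t) < C - bnd) lo = std::max(lo, 1.0 - f(t));
      if (alpha(t) > bnd) hi = std::min(hi, 1.0 - f(t));
    } else {
      if (alpha(t) < C - bnd) hi = std::min(hi, -1.0 - f(t));
      if (alpha(t) > bnd) lo = std::max(lo, -1.0 - f(t));
    }
  }
  if (std::isfinite(lo) && std::isfinite(hi)) m.b = 0.5 * (lo + hi);
  else if (std::isfinite(lo)) m.b = lo;
  else if (std::isfinite(hi)) m.b = hi;
  else m.b = 0.0;
  return m;
}

// fraction of correctly classified rows (labels +/-1); ties (decision
// value exactly 0) count as errors for both classes
double accOf(const LinSVM& m, const mat& Xt, const vec& yt) {
  vec dec = Xt * m.w + m.b;
  int correct = 0;
  for (uword i = 0; i < yt.n_elem; ++i)
    if (dec(i) * yt(i) > 0) ++correct;
  return static_cast<double>(correct) / yt.n_elem;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cppSvmTrain")]]
Rcpp::List cppSvmTrain(const arma::mat& X, const arma::vec& y,
                       double cost) {
  LinSVM m = smoTrain(X, y, cost);
  return Rcpp::List::create(Rcpp::Named("w") = m.w,
                            Rcpp::Named("b") = m.b);
}

// A, B: channels x timepoints x supertrials cubes for the two classes.
// Leave-one-supertrial-out cross-validation at each timepoint; returns
// percent correct per timepoint averaged over folds and test points.
// [[Rcpp::export(name = "cppPairDecode")]]
arma::vec cppPairDecode(const arma::cube& A, const arma::cube& B,
                        double cost) {
  const int T = A.n_cols;
  const int G = A.n_slices;
  const int Cn = A.n_rows;
  vec acc(T, fill::zeros);
  mat Xtr(2 * (G - 1), Cn);
  vec ytr(2 * (G - 1));
  mat Xte(2, Cn);
  vec yte = {1.0, -1.0};
  for (int t = 0; t < T; ++t) {
    double a = 0.0;
    for (int f = 0; f < G; ++f) {
      int r = 0;
      for (int g = 0; g < G; ++g) {
        if (g == f) continue;
        Xtr.row(r) = A.slice(g).col(t).t();
        ytr(r++) = 1.0;
      }
      for (int g = 0; g < G; ++g) {
        if (g == f) continue;
        Xtr.row(r) = B.slice(g).col(t).t();
        ytr(r++) = -1.0;
      }
      Xte.row(0) = A.slice(f).col(t).t();
      Xte.row(1) = B.slice(f).col(t).t();
      LinSVM m = smoTrain(Xtr, ytr, cost);
      a += accOf(m, Xte, yte);
    }
    acc(t) = 100.0 * a / G;
  }
  return acc;
}

// All pairwise decodings among a list of channels x timepoints x
// supertrials cubes (one per condition); returns the per-timepoint
// accuracy averaged over all condition pairs.
// [[Rcpp::export(name = "cppAllPairsDecode")]]
arma::vec cppAllPairsDecode(const Rcpp::List& condCubes, double cost) {
  const int nc = condCubes.size();
  if (nc < 2) Rcpp::stop("need at least 2 conditions for pairwise decoding");
  std::vector<cube> cubes(nc);
  for (int i = 0; i < nc; ++i)
    cubes[i] = Rcpp::as<cube>(condCubes[i]);
  vec acc(cubes[0].n_cols, fill::zeros);
  int npair = 0;
  for (int i = 0; i < nc - 1; ++i)
    for (int j = i + 1; j < nc; ++j) {
      acc += cppPairDecode(cubes[i], cubes[j], cost);
      ++npair;
    }
  return acc / npair;
}

// Cross-decoding: train on all supertrials of the training modality
// (cubes A1 vs A2), test on all supertrials of the test modality
// (B1 vs B2), independently at each timepoint.
// [[Rcpp::export(name = "cppPairCrossDecode")]]
arma::vec cppPairCrossDecode(const arma::cube& A1, const arma::cube& A2,
                             const arma::cube& B1, const arma::cube& B2,
                             double cost) {
  const int T = A1.n_cols;
  const int G = A1.n_slices;
  const int Gt = B1.n_slices;
  const int Cn = A1.n_rows;
  vec acc(T);
  mat Xtr(2 * G, Cn);
  vec ytr(2 * G);
  mat Xte(2 * Gt, Cn);
  vec yte(2 * Gt);
  for (int g = 0; g < G; ++g) { ytr(g) = 1.0; ytr(G + g) = -1.0; }
  for (int g = 0; g < Gt; ++g) { yte(g) = 1.0; yte(Gt + g) = -1.0; }
  for (int t = 0; t < T; ++t) {
    for (int g = 0; g < G; ++g) {
      Xtr.row(g) = A1.slice(g).col(t).t();
      Xtr.row(G + g) = A2.slice(g).col(t).t();
    }
    for (int g = 0; g < Gt; ++g) {
      Xte.row(g) = B1.slice(g).col(t).t();
      Xte.row(Gt + g) = B2.slice(g).col(t).t();
    }
    LinSVM m = smoTrain(Xtr, ytr, cost);
    acc(t) = 100.0 * accOf(m, Xte, yte);
  }
  return acc;
}

// Temporal generalization: train at every timepoint of the training
// modality, test at every timepoint of the test modality. Returns a
// trainT x testT accuracy matrix.
// [[Rcpp::export(name = "cppPairTimeGen")]]
arma::mat cppPairTimeGen(const arma::cube& A1, const arma::cube& A2,
                         const arma::cube& B1, const arma::cube& B2,
                         double cost) {
  const int T = A1.n_cols;
  const int G = A1.n_slices;
  const int Gt = B1.n_slices;
  const int Cn = A1.n_rows;
  mat acc(T, T);
  mat Xtr(2 * G, Cn);
  vec ytr(2 * G);
  for (int g = 0; g < G; ++g) { ytr(g) = 1.0; ytr(G + g) = -1.0; }
  for (int tr = 0; tr < T; ++tr) {
    for (int g = 0; g < G; ++g) {
      Xtr.row(g) = A1.slice(g).col(tr).t();
      Xtr.row(G + g) = A2.slice(g).col(tr).t();
    }
    LinSVM m = smoTrain(Xtr, ytr, cost);
    // linear decision values over all test timepoints at once
    rowvec wt = m.w.t();
    mat dec1(Gt, T), dec2(Gt, T);
    for (int g = 0; g < Gt; ++g) {
      dec1.row(g) = wt * B1.slice(g) + m.b;
      dec2.row(g) = wt * B2.slice(g) + m.b;
    }
    for (int te = 0; te < T; ++te) {
      int correct = 0;
      for (int g = 0; g < Gt; ++g) {
        if (dec1(g, te) > 0) ++correct;
        if (dec2(g, te) < 0) ++correct;
      }
      acc(tr, te) = 100.0 * correct / (2.0 * Gt);
    }
  }
  return acc;
}

// Leave-one-exemplar-out decoding: X is channels x timepoints x
// exemplars with labels y (+/-1); at each timepoint, each exemplar is
// held out in turn, the SVM trained on the rest, and the held-out
// exemplar classified.
// [[Rcpp::export(name = "cppLoocvDecode")]]
arma::vec cppLoocvDecode(const arma::cube& X, const arma::vec& y,
                         double cost) {
  const int T = X.n_cols;
  const int n = X.n_slices;
  const int Cn = X.n_rows;
  vec acc(T, fill::zeros);
  mat Xtr(n - 1, Cn);
  vec ytr(n - 1);
  for (int t = 0; t < T; ++t) {
    int correct = 0;
    for (int h = 0; h < n; ++h) {
      int r = 0;
      for (int i = 0; i < n; ++i) {
        if (i == h) continue;
        Xtr.row(r) = X.slice(i).col(t).t();
        ytr(r++) = y(i);
      }
      LinSVM m = smoTrain(Xtr, ytr, cost);
      double dec = dot(m.w, X.slice(h).col(t)) + m.b;
      if (dec * y(h) > 0) ++correct;
    }
    acc(t) = 100.0 * correct / n;
  }
  return acc;
}
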