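// LogitBoost with decision stumps (two-class, Friedman-Hastie-Tibshirani
// working response formulation) plus a staged leave-one-out evaluation used
// to pick the iteration count. Kept in C++ because LOOCV refits the whole
// boosting path once per training row; feature orders are sorted once and
// shared across all leave-one-out fits.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Stump {
  int feature;        // 0-based
  double threshold;   // x <= threshold -> left
  double left, right; // F-contributions (already halved)
};

static const double P_CLIP = 1e-5;
static const double Z_CLIP = 4.0;

struct BoostData {
  int n, p;
  std::vector<double> X;              // column-major
  std::vector<std::vector<int> > ord; // per-feature ascending order
  std::vector<int> y;

  BoostData(const NumericMatrix &Xm, const IntegerVector &yv)
    : n(Xm.nrow()), p(Xm.ncol()), X((size_t)Xm.nrow() * Xm.ncol()),
      ord(Xm.ncol()), y(yv.begin(), yv.end()) {
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i)
        X[(size_t)j * n + i] = Xm(i, j);
    for (int j = 0; j < p; ++j) {
      ord[j].resize(n);
      for (int i = 0; i < n; ++i) ord[j][i] = i;
      const double *xj = &X[(size_t)j * n];
      std::sort(ord[j].begin(), ord[j].end(), [xj](int a, int b) {
        if (xj[a] != xj[b]) return xj[a] < xj[b];
        return a < b;
      });
    }
  }
};

// One boosting run on all rows except `skip` (-1 = none). When `skip` is a
// valid row, `staged` receives the staged score F(x_skip) per iteration.
static void boost_path(const BoostData &d, int skip, int iters,
                       std::vector<Stump> &path,
                       std::vector<double> *staged) {
  int n = d.n, p = d.p;
  std::vector<double> F(n, 0.0), w(n), z(n);
  double Fh = 0.0;

  for (int it = 0; it < iters; ++it) {
    double TW = 0.0, TZ = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == skip) continue;
      double pr = 1.0 / (1.0 + std::exp(-2.0 * F[i]));
      if (pr < P_CLIP) pr = P_CLIP;
      if (pr > 1.0 - P_CLIP) pr = 1.0 - P_CLIP;
      double zi = ((double)d.y[i] - pr) / (pr * (1.0 - pr));
      if (zi > Z_CLIP) zi = Z_CLIP;
      if (zi < -Z_CLIP) zi = -Z_CLIP;
      w[i] = pr * (1.0 - pr);
      z[i] = zi;
      TW += w[i];
      TZ += w[i] * zi;
    }

    // best weighted-LS stump: maximize WL_z^2/WL_w + WR_z^2/WR_w; ties go
    // to the lowest feature index, then the lowest threshold (strict >)
    int best_j = -1;
    double best_gain = -1.0, best_thr = 0.0;
    for (int j = 0; j < p; ++j) {
      const double *xj = &d.X[(size_t)j * n];
      const std::vector<int> &oj = d.ord[j];
      double cw = 0.0, cz = 0.0;
      int prev = -1;
      for (int m = 0; m < n; ++m) {
        int i = oj[m];
        if (i == skip) continue;
        if (prev >= 0 && xj[i] != xj[prev] && cw > 0.0 && TW - cw > 0.0) {
          double rw = TW - cw, rz = TZ - cz;
          double gain = cz * cz / cw + rz * rz / rw;
          if (gain > best_gain) {
            best_gain = gain;
            best_j = j;
            best_thr = 0.5 * (xj[prev] + xj[i]);
          }
        }
        cw += w[i];
        cz += w[i] * z[i];
        prev = i;
      }
    }

    Stump st;
    if (best_j < 0) {
      // all rows identical on every feature: constant stump
      double c = (TW > 0.0) ? TZ / TW : 0.0;
      st.feature = 0;
      st.threshold = R_PosInf;
      st.left = st.right = 0.5 * c;
    } else {
      const double *xj = &d.X[(size_t)best_j * n];
      double lw = 0.0, lz = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i == skip || xj[i] > best_thr) continue;
        lw += w[i];
        lz += w[i] * z[i];
      }
      double rw = TW - lw, rz = TZ - lz;
      st.feature = best_j;
      st.threshold = best_thr;
      st.left = 0.5 * (lz / lw);
      st.right = 0.5 * (rz / rw);
    }
    path.push_back(st);

    const double *xb = &d.X[(size_t)st.feature * n];
    for (int i = 0; i < n; ++i) {
      if (i == skip) continue;
      F[i] += (xb[i] <= st.threshold) ? st.left : st.right;
    }
    if (staged != NULL) {
      Fh += (xb[skip] <= st.threshold) ? st.left : st.right;
      staged->push_back(Fh);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_logitboost_fit(NumericMatrix X, IntegerVector y, int iters) {
  BoostData d(X, y);
  std::vector<Stump> path;
  boost_path(d, -1, iters, path, NULL);
  int m = (int)path.size();
  IntegerVector feat(m);
  NumericVector thr(m), lv(m), rv(m);
  for (int i = 0; i < m; ++i) {
    feat[i] = path[i].feature + 1;
    thr[i] = path[i].threshold;
    lv[i] = path[i].left;
    rv[i] = path[i].right;
  }
  return DataFrame::create(_["feature"] = feat, _["threshold"] = thr,
                           _["left"] = lv, _["right"] = rv);
}

// [[Rcpp::export]]
NumericMatrix cpp_logitboost_predict(NumericMatrix X, IntegerVector feature,
                                     NumericVector threshold,
                                     NumericVector left, NumericVector right,
                                     int iters) {
  int n = X.nrow();
  NumericMatrix out(n, 1);
  int m = std::min((int)feature.size(), iters);
  for (int s = 0; s < m; ++s) {
    int j = feature[s] - 1;
    for (int i = 0; i < n; ++i)
      out(i, 0) += (X(i, j) <= threshold[s]) ? left[s] : right[s];
  }
  return out;
}

// Staged LOOCV accuracy: entry [it] = fraction of held-out rows classified
// correctly (F > 0 => class 1) by a model trained on the other rows for
// it + 1 boosting iterations.
// [[Rcpp::export]]
NumericVector cpp_logitboost_loocv(NumericMatrix X, IntegerVector y,
                                   int max_iters) {
  BoostData d(X, y);
  NumericVector acc(max_iters);
  for (int i = 0; i < d.n; ++i) {
    std::vector<Stump> path;
    std::vector<double> staged;
    staged.reserve(max_iters);
    boost_path(d, i, max_iters, path, &staged);
    for (int it = 0; it < max_iters; ++it) {
      int pred = staged[it] > 0.0 ? 1 : 0;
      if (pred == d.y[i]) acc[it] += 1.0;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  for (int it = 0; it < max_iters; ++it) acc[it] /= (double)d.n;
  return acc;
}
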