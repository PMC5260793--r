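#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cross-validated accuracy for a batch of gene masks.
//
// Each fold carries sufficient statistics of its training split computed
// once per run on all genes (per-class sums and sums of squares, class
// counts) plus the held-out matrix and labels. Masked-statistic extraction
// is then a row subset, so evaluating one mask costs O(retained * K)
// for the model plus O(retained * K * n_test) for prediction per fold.
//
// classifier: 0 = nearest centroid, 1 = nearest shrunken centroid (fitted
// and shrunk by `delta` inside every training fold; a fold in which no gene
// survives shrinkage scores 0, as does an all-zero mask upstream).
//
// Ties in the nearest-centroid argmin go to the lowest class index, matching
// the R implementation's deterministic rule.
// [[Rcpp::export]]
NumericVector cpp_cv_accuracy(IntegerMatrix masks, List folds,
                              int classifier, double delta) {
  const int d = masks.nrow();
  const int P = masks.ncol();
  const int nf = folds.size();
  NumericVector out(P);

  // unpack fold data once
  std::vector<NumericMatrix> sums(nf), ssq(nf), xtest(nf);
  std::vector<IntegerVector> counts(nf), ytest(nf);
  for (int f = 0; f < nf; ++f) {
    List fl = folds[f];
    sums[f] = as<NumericMatrix>(fl["sums"]);
    ssq[f] = as<NumericMatrix>(fl["ssq"]);
    counts[f] = as<IntegerVector>(fl["counts"]);
    xtest[f] = as<NumericMatrix>(fl["x_test"]);
    ytest[f] = as<IntegerVector>(fl["y_test"]);
  }
  const int K = counts[0].size();

  std::vector<int> idx;
  idx.reserve(d);
  std::vector<double> cent, xbar, s, dsh, denom, svec;

  for (int j = 0; j < P; ++j) {
    idx.clear();
    for (int i = 0; i < d; ++i) {
      if (masks(i, j) == 1) idx.push_back(i);
    }
    const int nk = (int)idx.size();
    if (nk == 0) { out[j] = 0.0; continue; }

    double acc_sum = 0.0;
    for (int f = 0; f < nf; ++f) {
      const NumericMatrix& S = sums[f];
      const NumericMatrix& Q = ssq[f];
      const IntegerVector& cnt = counts[f];
      const NumericMatrix& X = xtest[f];
      const IntegerVector& y = ytest[f];
      const int m = X.ncol();
      int n_tr = 0;
      for (int k = 0; k < K; ++k) n_tr += cnt[k];

      cent.assign((size_t)nk * K, 0.0);
      for (int k = 0; k < K; ++k) {
        const double inv = 1.0 / cnt[k];
        for (int r = 0; r < nk; ++r) cent[(size_t)k * nk + r] = S(idx[r], k) * inv;
      }

      int correct = 0;
      if (classifier == 0) {
        for (int t = 0; t < m; ++t) {
          int bestk = 0;
          double bestdist = R_PosInf;
          for (int k = 0; k < K; ++k) {
            double dist = 0.0;
            const double* ck = &cent[(size_t)k * nk];
            for (int r = 0; r < nk; ++r) {
              const double diff = X(idx[r], t) - ck[r];
              dist += diff * diff;
            }
            if (dist < bestdist) { bestdist = dist; bestk = k; }
          }
          if (bestk + 1 == y[t]) ++correct;
        }
      } else {
        // shrunken centroids: standardize class deviations, soft-threshold
        xbar.assign(nk, 0.0);
        s.assign(nk, 0.0);
        for (int r = 0; r < nk; ++r) {
          double tot = 0.0, pooled = 0.0;
          for (int k = 0; k < K; ++k) {
            tot += S(idx[r], k);
            const double c = cent[(size_t)k * nk + r];
            pooled += Q(idx[r], k) - cnt[k] * c * c;
          }
          xbar[r] = tot / n_tr;
          double s2 = pooled / (n_tr - K);
          s[r] = s2 > 0.0 ? std::sqrt(s2) : 0.0;
        }
        svec = s;
        std::sort(svec.begin(), svec.end());
        const double s0 = svec[(nk - 1) / 2];  // lower median

        dsh.assign((size_t)nk * K, 0.0);
        denom.assign((size_t)nk * K, 0.0);
        std::vector<bool> survives(nk, false);
        for (int k = 0; k < K; ++k) {
          const double mk = std::sqrt(1.0 / cnt[k] - 1.0 / n_tr);
          for (int r = 0; r < nk; ++r) {
            const double den = mk * (s[r] + s0);
            denom[(size_t)k * nk + r] = den;
            double dk = 0.0;
            if (den > 0.0) dk = (cent[(size_t)k * nk + r] - xbar[r]) / den;
            const double mag = std::abs(dk) - delta;
            double v = 0.0;
            if (mag > 0.0) v = (dk > 0 ? mag : -mag);
            dsh[(size_t)k * nk + r] = v;
            if (v != 0.0) survives[r] = true;
          }
        }
        std::vector<int> srows;
        srows.reserve(nk);
        for (int r = 0; r < nk; ++r) {
          if (survives[r]) srows.push_back(r);
        }
        if (srows.empty()) { acc_sum += 0.0; continue; }
        for (int t = 0; t < m; ++t) {
          int bestk = 0;
          double bestdist = R_PosInf;
          for (int k = 0; k < K; ++k) {
            double dist = 0.0;
            for (size_t q = 0; q < srows.size(); ++q) {
              const int r = srows[q];
              const double xprime = xbar[r] +
                denom[(size_t)k * nk + r] * dsh[(size_t)k * nk + r];
              const double diff = X(idx[r], t) - xprime;
              dist += diff * diff;
            }
            if (dist < bestdist) { bestdist = dist; bestk = k; }
          }
          if (bestk + 1 == y[t]) ++correct;
        }
      }
      acc_sum += (double)correct / m;
    }
    out[j] = acc_sum / nf;
  }
  return out;
}
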