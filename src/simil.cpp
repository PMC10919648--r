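// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <Rmath.h>
#include <algorithm>
using namespace Rcpp;

// Voxelwise correlation + per-map Benjamini-Hochberg + VOI statistics,
// vectorized over feature regressors.
//
// F: T x nF matrix of standardized regressors (zero mean, unit SD).
// Z: T x nV matrix of standardized voxel series (constant voxels must be
//    all-zero columns; they get r = 0 and are never significant).
// voi: 0-based indices of VOI voxels.
// alpha: BH level over the whole map (all nV voxels).
//
// Because the two-sided p-value of Pearson r is strictly decreasing in |r|
// at fixed df, the BH step-up over p-values is equivalent to a step-up over
// |r| against precomputed per-rank critical values rcrit_k (two-sided level
// k*alpha/m). The number of rejections k* = max{k : N(k) >= k} with
// N(k) = #{v : |r_v| >= rcrit_k} is found by histogramming ranks; the
// rejection set is {|r| >= k*-th largest |r|}, which reproduces the standard
// step-up (ties at the boundary are all rejected, as with p.adjust).
//
// Returns nF x 5 matrix: n_sig_total, n_sig_voi, mean_abs_r, max_abs_r,
// overlap (n_sig_voi / |voi|).
// [[Rcpp::export(name = ".simil_scan_cpp")]]
NumericMatrix simil_scan_cpp(const arma::mat& F, const arma::mat& Z,
                             IntegerVector voi, double alpha) {
  const int T = (int)F.n_rows, nF = (int)F.n_cols, nV = (int)Z.n_cols;
  const int df = T - 2;
  const int nvoi = voi.size();
  NumericMatrix out(nF, 5);

  // per-rank |r| critical values, decreasing in k
  std::vector<double> rcrit(nV);
  for (int k = 1; k <= nV; ++k) {
    double q = (double)k * alpha / nV;
    double tc = ::Rf_qt(1.0 - q / 2.0, (double)df, 1, 0);
    rcrit[k - 1] = tc / std::sqrt(df + tc * tc);
  }

  const int BLK = 512;
  arma::mat R;
  std::vector<double> absr(nV), tmp(nV);
  std::vector<int> hist(nV + 2);

  for (int f0 = 0; f0 < nF; f0 += BLK) {
    int nb = std::min(BLK, nF - f0);
    R = F.cols(f0, f0 + nb - 1).t() * Z;   // nb x nV, r * (T-1)
    const double inv = 1.0 / (double)(T - 1);
    for (int j = 0; j < nb; ++j) {
      for (int v = 0; v < nV; ++v) {
        double r = R(j, v) * inv;
        if (r > 1) r = 1; else if (r < -1) r = -1;
        absr[v] = std::fabs(r);
      }
      // only voxels clearing the loosest per-rank threshold can ever be
      // counted by the step-up; collect them first (few under the null)
      int ncand = 0;
      const double rmin = rcrit[nV - 1];
      for (int v = 0; v < nV; ++v)
        if (absr[v] >= rmin) tmp[ncand++] = absr[v];
      int kstar = 0;
      if (ncand > 0) {
        // rank histogram: k0(v) = smallest k with absr[v] >= rcrit[k-1]
        std::fill(hist.begin(), hist.begin() + nV + 2, 0);
        for (int j = 0; j < ncand; ++j) {
          double a = tmp[j];
          int lo = 0, hi = nV - 1;      // first index with rcrit <= a
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (rcrit[mid] <= a) hi = mid; else lo = mid + 1;
          }
          ++hist[lo + 1];               // k0 = lo + 1 (1-based)
        }
        // N(k) <= ncand, so the step-up can never settle beyond ncand
        int cum = 0;
        const int kmax_ = std::min(nV, ncand);
        for (int k = 1; k <= kmax_; ++k) {
          cum += hist[k];               // N(k)
          if (cum >= k) kstar = k;
        }
      }
      double thr = R_PosInf;
      if (kstar > 0) {
        std::nth_element(tmp.begin(), tmp.begin() + (kstar - 1),
                         tmp.begin() + ncand, std::greater<double>());
        thr = tmp[kstar - 1];
      }
      int nsig = 0, nsv = 0;
      double smean = 0, smax = 0;
      if (kstar > 0) {
        for (int v = 0; v < nV; ++v) if (absr[v] >= thr) ++nsig;
        for (int i = 0; i < nvoi; ++i) {
          double a = absr[voi[i]];
          if (a >= thr) { ++nsv; smean += a; if (a > smax) smax = a; }
        }
      }
      int row = f0 + j;
      out(row, 0) = nsig;
      out(row, 1) = nsv;
      out(row, 2) = nsv > 0 ? smean / nsv : 0.0;
      out(row, 3) = smax;
      out(row, 4) = nvoi > 0 ? (double)nsv / nvoi : 0.0;
    }
  }
  return out;
}

// Regressor conditioning for the bulk scan: per feature column,
// standardize, causal-convolve with the kernel (zero pre-pad, same length),
// standardize again. Columns with zero variance at either stage are zeroed
// and flagged. V: T x F (one feature per column); h: kernel weights.
// [[Rcpp::export(name = ".prep_regressors_cpp")]]
List prep_regressors_cpp(const arma::mat& V, const arma::vec& h) {
  const int T = (int)V.n_rows, F = (int)V.n_cols, K = (int)h.n_elem;
  arma::mat out(T, F);
  LogicalVector ok(F);
  std::vector<double> buf(T);
  for (int f = 0; f < F; ++f) {
    const double* x = V.colptr(f);
    double* y = out.colptr(f);
    double m = 0;
    for (int t = 0; t < T; ++t) m += x[t];
    m /= T;
    double ss = 0;
    for (int t = 0; t < T; ++t) { double d = x[t] - m; ss += d * d; }
    double sd = std::sqrt(ss / (T - 1));
    if (!(sd > 0) || !std::isfinite(sd)) {
      ok[f] = false;
      std::fill(y, y + T, 0.0);
      continue;
    }
    for (int t = 0; t < T; ++t) buf[t] = (x[t] - m) / sd;
    for (int t = 0; t < T; ++t) {
      double acc = 0;
      int jm = std::min(K - 1, t);
      for (int j = 0; j <= jm; ++j) acc += h[j] * buf[t - j];
      y[t] = acc;
    }
    double m2 = 0;
    for (int t = 0; t < T; ++t) m2 += y[t];
    m2 /= T;
    double ss2 = 0;
    for (int t = 0; t < T; ++t) { double d = y[t] - m2; ss2 += d * d; }
    double sd2 = std::sqrt(ss2 / (T - 1));
    if (!(sd2 > 0) || !std::isfinite(sd2)) {
      ok[f] = false;
      std::fill(y, y + T, 0.0);
      continue;
    }
    for (int t = 0; t < T; ++t) y[t] = (y[t] - m2) / sd2;
    ok[f] = true;
  }
  return List::create(_["values"] = out, _["ok"] = ok);
}

// Plain voxelwise Pearson r for one regressor (reference path for maps).
// [[Rcpp::export(name = ".pearson_cols_cpp")]]
NumericVector pearson_cols_cpp(const arma::vec& x, const arma::mat& Z) {
  const int T = (int)Z.n_rows, nV = (int)Z.n_cols;
  NumericVector r(nV);
  double mx = arma::mean(x);
  arma::vec xc = x - mx;
  double sx = std::sqrt(arma::dot(xc, xc));
  for (int v = 0; v < nV; ++v) {
    arma::vec z = Z.col(v);
    double mz = arma::mean(z);
    double num = 0, sz = 0;
    for (int t = 0; t < T; ++t) {
      double d = z[t] - mz;
      num += xc[t] * d; sz += d * d;
    }
    double den = sx * std::sqrt(sz);
    r[v] = den > 0 ? num / den : 0.0;
  }
  return r;
}
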