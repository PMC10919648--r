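#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-channel, per-window EEG feature bank. Row layout per channel (35 rows):
//  1 mean, 2 mean_norm, 3 sd, 4 skewness, 5 kurtosis,
//  6 hjorth_activity, 7 hjorth_mobility, 8 hjorth_complexity,
//  9 total_power, 10-14 abs band powers (delta..gamma),
//  15-19 rel band powers, 20-29 band ratios (lower/higher, pair order
//  delta_theta, delta_alpha, delta_beta, delta_gamma, theta_alpha, theta_beta,
//  theta_gamma, alpha_beta, alpha_gamma, beta_gamma),
//  30 mean_freq, 31 alpha_peak_freq, 32 beta/(theta+alpha),
//  33 theta/(alpha+beta), 34 higuchi_fd, 35 hurst_rs
// Values that an estimator cannot produce are NaN and flagged in `missing`.

static const int NFEAT = 35;

static double var_n1(const double* x, int n, double* mean_out) {
  double m = 0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) { double d = x[i] - m; s += d * d; }
  if (mean_out) *mean_out = m;
  return s / (n - 1);
}

static double higuchi_fd(const double* x, int n, int kmax) {
  std::vector<double> lx, lk;
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0; int nm = 0;
    for (int m = 0; m < k; ++m) {
      int np = (n - 1 - m) / k;
      if (np < 1) continue;
      double s = 0;
      for (int i = 1; i <= np; ++i) s += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      Lk += s * ((double)(n - 1) / ((double)np * k)) / k;
      ++nm;
    }
    if (nm == 0) continue;
    Lk /= nm;
    if (Lk <= 0) return NA_REAL;
    lx.push_back(std::log((double)k));
    lk.push_back(std::log(Lk));
  }
  int m = (int)lx.size();
  if (m < 2) return NA_REAL;
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += lx[i]; my += lk[i]; }
  mx /= m; my /= m;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < m; ++i) { sxy += (lx[i] - mx) * (lk[i] - my); sxx += (lx[i] - mx) * (lx[i] - mx); }
  return -sxy / sxx;
}

static double hurst_rs(const double* x, int n) {
  std::vector<double> ls, lrs;
  std::vector<double> w;
  for (int s = 16; s <= n / 2; s *= 2) {
    int nblk = n / s;
    double rs = 0; int nv = 0;
    for (int b = 0; b < nblk; ++b) {
      const double* y = x + b * s;
      double m = 0;
      for (int i = 0; i < s; ++i) m += y[i];
      m /= s;
      double cum = 0, mn = 0, mx = 0, ss = 0;
      for (int i = 0; i < s; ++i) {
        double d = y[i] - m;
        ss += d * d;
        cum += d;
        if (cum < mn) mn = cum;
        if (cum > mx) mx = cum;
      }
      double S = std::sqrt(ss / s);
      if (S > 0) { rs += (mx - mn) / S; ++nv; }
    }
    if (nv == 0) continue;
    ls.push_back(std::log((double)s));
    lrs.push_back(std::log(rs / nv));
  }
  int m = (int)ls.size();
  if (m < 2) return NA_REAL;
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += ls[i]; my += lrs[i]; }
  mx /= m; my /= m;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < m; ++i) { sxy += (ls[i] - mx) * (lrs[i] - my); sxx += (ls[i] - mx) * (ls[i] - mx); }
  return sxy / sxx;
}

// Per-row quartiles (type-7, as stats::quantile) for the outlier screen.
// [[Rcpp::export(name = ".row_quartiles_cpp")]]
NumericMatrix row_quartiles_cpp(NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nr, 3);
  std::vector<double> buf(nc);
  const double probs[3] = {0.25, 0.5, 0.75};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) buf[c] = X(r, c);
    std::sort(buf.begin(), buf.end());
    for (int q = 0; q < 3; ++q) {
      double h = probs[q] * (nc - 1);
      int lo = (int)h;
      double g = h - lo;
      out(r, q) = (1 - g) * buf[lo] + (lo + 1 < nc ? g * buf[lo + 1] : 0);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".extract_features_cpp")]]
List extract_features_cpp(NumericMatrix X, int fs, int kmax) {
  const int nsamp = X.nrow(), nchan = X.ncol();
  const int nwin = nsamp / fs;
  const int L = fs / 2;          // Welch segment length -> 2 Hz grid
  const int hop = L / 2;
  const int nseg = (fs - L) / hop + 1;
  const int NB = 23;             // DFT bins 0..22 -> 0..44 Hz
  const double df = (double)fs / L;

  NumericMatrix vals(NFEAT * nchan, nwin);
  LogicalMatrix miss(NFEAT * nchan, nwin);

  // Hamming window (symmetric) and its power
  std::vector<double> w(L);
  double U = 0;
  for (int i = 0; i < L; ++i) {
    w[i] = 0.54 - 0.46 * std::cos(2.0 * M_PI * i / (L - 1));
    U += w[i] * w[i];
  }
  std::vector<double> coef(NB);
  for (int k = 0; k < NB; ++k) coef[k] = 2.0 * std::cos(2.0 * M_PI * k / L);

  // band bin ranges on the 2 Hz grid: [0,4) [4,8) [8,13) [13,30) [30,45]
  const int blo[5] = {0, 2, 4, 7, 15};
  const int bhi[5] = {1, 3, 6, 14, 22};   // inclusive
  // unordered band pairs, numerator = lower band
  const int pr_lo[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
  const int pr_hi[10] = {1, 2, 3, 4, 2, 3, 4, 3, 4, 4};

  std::vector<double> wx(L), d1(fs), d2(fs), psd(NB);

  for (int c = 0; c < nchan; ++c) {
    const double* ch = &X(0, c);
    double run_mean;
    double run_sd = std::sqrt(var_n1(ch, nsamp, &run_mean));
    const int r0 = c * NFEAT;

    for (int t = 0; t < nwin; ++t) {
      const double* x = ch + (size_t)t * fs;
      double* V = &vals(r0, t);
      double m, v;
      v = var_n1(x, fs, &m);
      double sd = std::sqrt(v);

      V[0] = m;
      V[1] = run_sd > 0 ? (m - run_mean) / run_sd : NA_REAL;
      V[2] = sd;
      if (v > 0) {
        double m3 = 0, m4 = 0;
        for (int i = 0; i < fs; ++i) {
          double d = x[i] - m, d2_ = d * d;
          m3 += d2_ * d; m4 += d2_ * d2_;
        }
        m3 /= fs; m4 /= fs;
        double m2 = 0;
        for (int i = 0; i < fs; ++i) { double d = x[i] - m; m2 += d * d; }
        m2 /= fs;
        V[3] = m3 / std::pow(m2, 1.5);
        V[4] = m4 / (m2 * m2);
      } else { V[3] = NA_REAL; V[4] = NA_REAL; }

      // Hjorth: first differences scaled by fs
      V[5] = v;
      if (v > 0) {
        for (int i = 0; i < fs - 1; ++i) d1[i] = (x[i + 1] - x[i]) * fs;
        double v1 = var_n1(d1.data(), fs - 1, nullptr);
        double mob = std::sqrt(v1 / v);
        V[6] = mob;
        if (v1 > 0) {
          for (int i = 0; i < fs - 2; ++i) d2[i] = (d1[i + 1] - d1[i]) * fs;
          double v2 = var_n1(d2.data(), fs - 2, nullptr);
          V[7] = std::sqrt(v2 / v1) / mob;
        } else V[7] = NA_REAL;
      } else { V[6] = NA_REAL; V[7] = NA_REAL; }

      // Welch PSD on the 2 Hz grid, bins 0..22 via a Goertzel resonator
      // bank (bins advanced together per sample: independent recurrences
      // interleave, hiding the per-resonator dependency latency)
      for (int k = 0; k < NB; ++k) psd[k] = 0;
      double s1[NB], s2[NB];
      for (int sgi = 0; sgi < nseg; ++sgi) {
        const double* xs = x + sgi * hop;
        for (int i = 0; i < L; ++i) wx[i] = xs[i] * w[i];
        for (int k = 0; k < NB; ++k) { s1[k] = 0; s2[k] = 0; }
        for (int i = 0; i < L; ++i) {
          double xi = wx[i];
          for (int k = 0; k < NB; ++k) {
            double s0 = xi + coef[k] * s1[k] - s2[k];
            s2[k] = s1[k]; s1[k] = s0;
          }
        }
        for (int k = 0; k < NB; ++k)
          psd[k] += s1[k] * s1[k] + s2[k] * s2[k] - coef[k] * s1[k] * s2[k];
      }
      for (int k = 0; k < NB; ++k) {
        double sc = (k == 0 ? 1.0 : 2.0) / ((double)fs * U * nseg);
        psd[k] *= sc;
      }

      double ab[5];
      double tot = 0;
      for (int b = 0; b < 5; ++b) {
        double s = 0;
        for (int k = blo[b]; k <= bhi[b]; ++k) s += psd[k];
        ab[b] = s * df;
        tot += ab[b];
      }
      V[8] = tot;
      for (int b = 0; b < 5; ++b) V[9 + b] = ab[b];
      for (int b = 0; b < 5; ++b) V[14 + b] = tot > 0 ? ab[b] / tot : NA_REAL;
      for (int p = 0; p < 10; ++p)
        V[19 + p] = ab[pr_hi[p]] > 0 ? ab[pr_lo[p]] / ab[pr_hi[p]] : NA_REAL;

      if (tot > 0) {
        double sf = 0, sp = 0;
        for (int k = 0; k < NB; ++k) { sf += (k * df) * psd[k]; sp += psd[k]; }
        V[29] = sf / sp;
        int kb = 4; double pb = psd[4];
        for (int k = 5; k <= 6; ++k) if (psd[k] > pb) { pb = psd[k]; kb = k; }
        V[30] = (pb > 0) ? kb * df : NA_REAL;
      } else { V[29] = NA_REAL; V[30] = NA_REAL; }

      double ta = ab[1] + ab[2], abv = ab[2] + ab[3];
      V[31] = ta > 0 ? ab[3] / ta : NA_REAL;
      V[32] = abv > 0 ? ab[1] / abv : NA_REAL;

      V[33] = (v > 0) ? higuchi_fd(x, fs, kmax) : NA_REAL;
      V[34] = (v > 0) ? hurst_rs(x, fs) : NA_REAL;
      if (ISNAN(V[33])) V[33] = NA_REAL;
      if (ISNAN(V[34])) V[34] = NA_REAL;

      for (int f = 0; f < NFEAT; ++f)
        miss(r0 + f, t) = ISNAN(V[f]);
    }
  }
  return List::create(_["values"] = vals, _["missing"] = miss);
}
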