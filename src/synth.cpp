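#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".rng_normal_cpp")]]
NumericVector rng_normal_cpp(int n, double seed, double key1, double key2) {
  SmRng g((uint64_t)seed, (uint64_t)key1, (uint64_t)key2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.rnorm();
  return out;
}

// [[Rcpp::export(name = ".rng_unif_cpp")]]
NumericVector rng_unif_cpp(int n, double seed, double key1, double key2) {
  SmRng g((uint64_t)seed, (uint64_t)key1, (uint64_t)key2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.runif();
  return out;
}

// IIR filter, direct form II transposed, zero initial state.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 double* x, int n) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int j = 0; j < ns; ++j) {
      double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      z[j] = bj * xi - aj * yi + (j + 1 < ns ? z[j + 1] : 0.0);
    }
    x[i] = yi;
  }
}

// Paul Kellet's economy pink-noise filter (1/f amplitude shaping of a
// white-noise stream); coefficients are fs-agnostic over the usable band.
struct PinkFilter {
  double b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0, b6 = 0;
  inline double step(double w) {
    b0 = 0.99886 * b0 + w * 0.0555179;
    b1 = 0.99332 * b1 + w * 0.0750759;
    b2 = 0.96900 * b2 + w * 0.1538520;
    b3 = 0.86650 * b3 + w * 0.3104856;
    b4 = 0.55000 * b4 + w * 0.5329522;
    b5 = -0.7616 * b5 - w * 0.0168980;
    double y = b0 + b1 + b2 + b3 + b4 + b5 + b6 + w * 0.5362;
    b6 = w * 0.115926;
    return y;
  }
};

static std::vector<double> as_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

static double sd_of(const double* x, int n) {
  double m = 0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) s += (x[i] - m) * (x[i] - m);
  return std::sqrt(s / (n - 1));
}

// Synthesize one run of multichannel EEG.
//
// Every channel: pink (1/f) background band-limited to the pass band, plus a
// sinusoidal rhythm at the responsive band's center frequency (independent
// random phase per channel) of relative RMS amplitude osc_rel. Channels
// flagged responsive have the rhythm multiplied by the envelope (held per
// 1-second block); the others use envelope 1, so a zero-gain envelope of 1
// leaves all channels statistically exchangeable.
//
// envelope: one value per second (length >= floor(nsamp / fs)).
// b_hp/a_hp, b_lp/a_lp: broadband band-limiting filters.
// f0_hz: rhythm carrier frequency.
// Returns nsamp x nchan matrix (one column per channel), microvolts.
// [[Rcpp::export(name = ".synth_eeg_cpp")]]
NumericMatrix synth_eeg_cpp(int nchan, int nsamp, int fs,
                            double seed, double run_key,
                            LogicalVector responsive,
                            NumericVector envelope,
                            NumericVector b_hp, NumericVector a_hp,
                            NumericVector b_lp, NumericVector a_lp,
                            double f0_hz, double amp_uv, double osc_rel) {
  NumericMatrix out(nsamp, nchan);
  std::vector<double> bhp = as_vec(b_hp), ahp = as_vec(a_hp);
  std::vector<double> blp = as_vec(b_lp), alp = as_vec(a_lp);
  const double TWOPI = 6.283185307179586476925287;

  for (int c = 0; c < nchan; ++c) {
    double* col = &out(0, c);
    // background: white -> pink -> band-limit
    SmRng g((uint64_t)seed, (uint64_t)run_key, (uint64_t)(2 * c + 1));
    PinkFilter pf;
    for (int i = 0; i < nsamp; ++i) col[i] = pf.step(g.rnorm());
    df2t(bhp, ahp, col, nsamp);
    df2t(blp, alp, col, nsamp);
    double sb = sd_of(col, nsamp);
    double k = amp_uv / sb;
    for (int i = 0; i < nsamp; ++i) col[i] *= k;

    if (osc_rel > 0) {
      SmRng go((uint64_t)seed, (uint64_t)run_key, (uint64_t)(2 * c + 2));
      double phi = TWOPI * go.runif();
      // amplitude for RMS amp_uv * osc_rel (sinusoid RMS = A / sqrt 2)
      double A = amp_uv * osc_rel * std::sqrt(2.0);
      double w = TWOPI * f0_hz / fs;
      // per-sample recurrence avoids 32M sin() calls; re-sync each second
      bool resp = responsive[c];
      for (int t0 = 0; t0 < nsamp; t0 += fs) {
        int tend = std::min(t0 + fs, nsamp);
        double env = resp ? envelope[t0 / fs] : 1.0;
        double Ae = A * env;
        double s = std::sin(w * t0 + phi), cs = std::cos(w * t0 + phi);
        double cw = std::cos(w), sw = std::sin(w);
        for (int i = t0; i < tend; ++i) {
          col[i] += Ae * s;
          double s2 = s * cw + cs * sw;
          cs = cs * cw - s * sw;
          s = s2;
        }
      }
    }
  }
  return out;
}
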