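#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>

using namespace Rcpp;

// Cubic B-spline kernel, support [-2, 2], unit integral.
static inline double bspline3(double u) {
  double a = std::fabs(u);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return 2.0 / 3.0 - a * a + 0.5 * a * a * a;
  double b = 2.0 - a;
  return b * b * b / 6.0;
}

// Tap table for the synaptic lowpass + resampler. Output sample j sits at
// t_j = j / out_fs; taps cover the kernel support 4*delta around t_j. The
// fractional alignment of t_j on the input grid cycles with a short period
// when fs / out_fs is rational, so tables are cached per phase.
struct TapSet {
  int n0;                    // first input sample (relative to floor(c_j))
  std::vector<double> w;     // normalized weights (sum = 1 -> unit DC gain)
};

static void build_taps(double fs, double out_fs, double delta, int n_out,
                       long long n_offset,
                       std::vector<TapSet>& phases, std::vector<int>& phase_of,
                       std::vector<long long>& base_of) {
  double step = fs / out_fs;
  int period = 0;
  for (int p = 1; p <= 4096; ++p) {
    double v = p * step;
    if (std::fabs(v - std::llround(v)) < 1e-9) { period = p; break; }
  }
  if (period == 0) period = n_out;  // no short cycle: one table per sample
  int half = (int)std::ceil(2.0 * delta * fs) + 1;
  phases.resize(period);
  phase_of.resize(n_out);
  base_of.resize(n_out);
  for (int j = 0; j < n_out; ++j) {
    phase_of[j] = j % period;
    base_of[j] = n_offset + (long long)std::floor(j * step);
  }
  for (int p = 0; p < period; ++p) {
    double c = p * step;                 // center in input samples
    long long lo = (long long)std::floor(c) - half;
    long long hi = (long long)std::floor(c) + half;
    TapSet ts;
    ts.n0 = (int)(lo - (long long)std::floor(c));
    double s = 0.0;
    for (long long n = lo; n <= hi; ++n) {
      double u = (c - (double)n) / (delta * fs);
      double wv = bspline3(u);
      ts.w.push_back(wv);
      s += wv;
    }
    for (size_t i = 0; i < ts.w.size(); ++i) ts.w[i] /= s;
    phases[p] = ts;
  }
}

//' @noRd
// [[Rcpp::export(name = ".gammatone_cochleogram_cpp")]]
NumericMatrix gammatone_cochleogram_cpp(NumericVector x, double fs,
                                        NumericVector cf, NumericVector bw,
                                        int order, double delta,
                                        double out_fs, int n_out,
                                        int n_offset) {
  const int N = x.size();
  const int K = cf.size();
  NumericMatrix out(n_out, K);

  std::vector<TapSet> phases;
  std::vector<int> phase_of;
  std::vector<long long> base_of;
  build_taps(fs, out_fs, delta, n_out, n_offset, phases, phase_of, base_of);

  const int LANES = 4;  // channels per pass: independent recursion chains
                        // overlap (ILP/SIMD) instead of serializing
  std::vector< std::vector<double> > env(LANES,
                                         std::vector<double>((size_t)N));

  for (int k0 = 0; k0 < K; k0 += LANES) {
    int nb = std::min(LANES, K - k0);
    double pr[LANES], pi[LANES], gain[LANES];
    for (int l = 0; l < nb; ++l) {
      int k = k0 + l;
      double r = std::exp(-2.0 * M_PI * bw[k] / fs);
      double th = 2.0 * M_PI * cf[k] / fs;
      pr[l] = r * std::cos(th);
      pi[l] = r * std::sin(th);
      // analytic gammatone: cascade of `order` identical complex one-poles;
      // peak gain of the cascade is (1 - r)^-order at the CF, and the
      // factor 2 recovers the Hilbert-envelope convention for real inputs
      gain[l] = 2.0 * std::pow(1.0 - r, (double)order);
    }
    for (int l = nb; l < LANES; ++l) { pr[l] = pi[l] = gain[l] = 0.0; }

    if (order == 4) {
      double z1r[LANES] = {0}, z1i[LANES] = {0}, z2r[LANES] = {0},
             z2i[LANES] = {0}, z3r[LANES] = {0}, z3i[LANES] = {0},
             z4r[LANES] = {0}, z4i[LANES] = {0};
      for (int n = 0; n < N; ++n) {
        double xn = x[n];
        for (int l = 0; l < LANES; ++l) {
          double tr;
          tr     = pr[l] * z1r[l] - pi[l] * z1i[l] + xn;
          z1i[l] = pr[l] * z1i[l] + pi[l] * z1r[l];            z1r[l] = tr;
          tr     = pr[l] * z2r[l] - pi[l] * z2i[l] + z1r[l];
          z2i[l] = pr[l] * z2i[l] + pi[l] * z2r[l] + z1i[l];   z2r[l] = tr;
          tr     = pr[l] * z3r[l] - pi[l] * z3i[l] + z2r[l];
          z3i[l] = pr[l] * z3i[l] + pi[l] * z3r[l] + z2i[l];   z3r[l] = tr;
          tr     = pr[l] * z4r[l] - pi[l] * z4i[l] + z3r[l];
          z4i[l] = pr[l] * z4i[l] + pi[l] * z4r[l] + z3i[l];   z4r[l] = tr;
          env[l][n] = std::sqrt(z4r[l] * z4r[l] + z4i[l] * z4i[l]);
        }
      }
    } else {
      for (int l = 0; l < nb; ++l) {
        std::vector<std::complex<double> > z((size_t)order,
                                             std::complex<double>(0, 0));
        std::complex<double> p(pr[l], pi[l]);
        for (int n = 0; n < N; ++n) {
          std::complex<double> in(x[n], 0.0);
          for (int s = 0; s < order; ++s) {
            z[s] = p * z[s] + in;
            in = z[s];
          }
          env[l][n] = std::abs(in);
        }
      }
    }

    for (int l = 0; l < nb; ++l) {
      const std::vector<double>& e = env[l];
      for (int j = 0; j < n_out; ++j) {
        const TapSet& ts = phases[phase_of[j]];
        long long n = base_of[j] + ts.n0;
        double acc = 0.0;
        for (size_t i = 0; i < ts.w.size(); ++i, ++n) {
          if (n >= 0 && n < N) acc += ts.w[i] * e[(size_t)n];
        }
        double v = acc * gain[l];
        out(j, k0 + l) = v > 0.0 ? v : 0.0;
      }
    }
  }
  return out;
}
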