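// Fast inner loop of the plasticity model: one simulated day of per-stimulus
// weight updates  w_ij <- max(0, w_ij + eps * rho(w_ij) * (k*u_j*v_i + xi)),
// with rho(w) = tanh(gain*w), v = W^T u, and xi ~ N(0, noise_sd^2) drawn
// independently per weight per stimulus.
//
// Performance notes (the loop touches n^2 weights per stimulus, ~10^7 times
// per simulated day at full scale): xi comes from a Ziggurat sampler over a
// xoshiro256++ generator, and rho is evaluated through a dense linear
// interpolation table of tanh (see TanhTable below). The pure-R reference
// path (plasticity_step) uses exact tanh and R's RNG; equivalence is
// asserted in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

inline uint64_t rotl(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Marsaglia-Tsang Ziggurat for the standard normal
struct Ziggurat {
  double x[257], y[257];
  Ziggurat() {
    const double r = 3.6541528853610088, v = 0.00492867323399;
    x[256] = v * std::exp(0.5 * r * r);
    x[255] = r;
    y[255] = std::exp(-0.5 * r * r);
    for (int i = 254; i >= 1; i--) {
      x[i] = std::sqrt(-2.0 * std::log(v / x[i + 1] +
                                       std::exp(-0.5 * x[i + 1] * x[i + 1])));
      y[i] = std::exp(-0.5 * x[i] * x[i]);
    }
    x[0] = 0.0; y[0] = 1.0;
  }
  inline double draw(Xoshiro& g) const {
    for (;;) {
      const uint64_t u = g.next();
      const int i = (int)(u & 0xff);
      const double f = ((u >> 9) * 0x1.0p-55) * 2.0 - 1.0;  // (-1, 1)
      const double z = f * x[i + 1];
      if (std::fabs(z) < x[i]) return z;
      if (i == 255) {  // tail beyond r
        const double r = 3.6541528853610088;
        double xx, yy;
        do {
          xx = -std::log(g.unif()) / r;
          yy = -std::log(g.unif());
        } while (yy + yy < xx * xx);
        return f > 0 ? r + xx : -(r + xx);
      }
      const double h = y[i + 1] + (y[i] - y[i + 1]) * g.unif();
      if (h < std::exp(-0.5 * z * z)) return z;
    }
  }
};

// dense linear-interpolation table of tanh on [0, 20] (value/slope pairs
// interleaved so each lookup touches one cache line); odd extension below 0,
// saturated to 1 beyond 20 (tanh(20) = 1 - 4e-18). Max abs error ~2.3e-9,
// far below the stochastic scale of the simulation; the exact-tanh reference
// path is plasticity_step() in R.
struct TanhTable {
  static const int N = 1 << 17;
  double h_, inv_h;
  std::vector<double> tab;  // [2*i] = value at x_i, [2*i+1] = slope on bin i
  TanhTable() : tab(2 * (N + 1)) {
    const double h = 20.0 / N;
    h_ = h;
    inv_h = 1.0 / h;
    for (int i = 0; i <= N; i++) {
      const double v = std::tanh(i * h);
      tab[2 * i] = v;
      tab[2 * i + 1] = (i < N) ? (std::tanh((i + 1) * h) - v) * inv_h : 0.0;
    }
    tab[2 * N + 1] = 0.0;
  }
  inline double eval(double x) const {
    const double ax = std::fabs(x);
    if (ax >= 20.0) return x < 0 ? -1.0 : 1.0;  // also guards the int cast
    const int i = (int)(ax * inv_h);
    const double r = tab[2 * i] + tab[2 * i + 1] * (ax - i * h_);
    return x < 0 ? -r : r;
  }
};

const Ziggurat ZIG;
const TanhTable TANH_TAB;

// minimal orientation distance; assumes both angles lie in [-180, 180)
inline double circ_dist180(double a, double b) {
  double d = std::fabs(a - b);
  while (d >= 180.0) d -= 180.0;
  return d > 90.0 ? 180.0 - d : d;
}

}  // namespace

// [[Rcpp::export(name = ".rho_table")]]
NumericVector rho_table(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) out[i] = TANH_TAB.eval(x[i]);
  return out;
}

// [[Rcpp::export(name = ".kernel_normal_sample")]]
NumericVector kernel_normal_sample(int m, double seed) {
  Xoshiro g((uint64_t)seed);
  NumericVector out(m);
  for (int i = 0; i < m; i++) out[i] = ZIG.draw(g);
  return out;
}

// One simulated day: n_steps stimulus presentations with plasticity.
// W: n x n, column i = incoming weights of postsynaptic neuron i.
// Returns the updated matrix (input untouched). seed and stream jointly
// seed an independent noise stream (stream = global day counter).
// [[Rcpp::export(name = ".sim_day")]]
NumericMatrix sim_day(NumericMatrix W, NumericVector centers,
                      NumericVector thetas, double amp, double offset,
                      double sigma_u, double eps, double k, double noise_sd,
                      double gain, bool clip, double seed, double stream) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("W must be square");
  if (centers.size() != n) stop("centers must have length nrow(W)");
  NumericMatrix Wout(clone(W));
  Xoshiro g(((uint64_t)seed) * 0x9e3779b97f4a7c15ULL + (uint64_t)stream);
  std::vector<double> u(n), v(n), noise(n), rho(n);
  const bool has_noise = noise_sd > 0.0;
  const bool has_hebb = k != 0.0;
  const double inv2s2 = 1.0 / (2.0 * sigma_u * sigma_u);
  double* Wp = REAL(Wout);

  for (R_xlen_t t = 0; t < thetas.size(); t++) {
    const double th = thetas[t];
    for (int j = 0; j < n; j++) {
      const double d = circ_dist180(th, centers[j]);
      u[j] = offset + amp * std::exp(-d * d * inv2s2);
    }
    if (has_hebb) {
      for (int i = 0; i < n; i++) {
        const double* col = Wp + (size_t)i * n;
        double s = 0.0;
        for (int j = 0; j < n; j++) s += col[j] * u[j];
        v[i] = s;
      }
    }
    for (int i = 0; i < n; i++) {
      double* col = Wp + (size_t)i * n;
      const double kv = has_hebb ? k * v[i] : 0.0;
      // buffered sub-loops keep the table lookups and the fused update
      // vectorizable; only the Ziggurat draw is inherently scalar
      for (int j = 0; j < n; j++) rho[j] = TANH_TAB.eval(gain * col[j]);
      if (has_noise) {
        for (int j = 0; j < n; j++) noise[j] = noise_sd * ZIG.draw(g);
        for (int j = 0; j < n; j++) {
          double w = col[j] + eps * rho[j] * (kv * u[j] + noise[j]);
          if (clip && w < 0) w = 0;
          col[j] = w;
        }
      } else {
        for (int j = 0; j < n; j++) {
          double w = col[j] + eps * rho[j] * (kv * u[j]);
          if (clip && w < 0) w = 0;
          col[j] = w;
        }
      }
    }
  }
  for (size_t q = 0; q < (size_t)n * n; q++) {
    if (!std::isfinite(Wp[q]))
      stop("numerical failure: non-finite weight after update");
  }
  return Wout;
}
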