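#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Counter-seeded xoshiro256++ stream with splitmix64 initialisation.
// Each (seed, stream) pair yields an independent, bit-reproducible sequence
// that does not touch R's global RNG state, so psychometric curves can be
// simulated one (combination, amplitude) cell at a time in any order.
namespace {

inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Ziggurat tables for the standard normal (128 layers, Marsaglia & Tsang)
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigTables zig;

struct RngStream {
  uint64_t s[4];

  RngStream(int seed, int stream) {
    uint64_t init = (static_cast<uint64_t>(static_cast<uint32_t>(seed)) << 32) ^
                    static_cast<uint64_t>(static_cast<uint32_t>(stream));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(init);
    for (int i = 0; i < 8; ++i) next(); // decorrelate low-entropy seeds
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1), never exactly 0 or 1
  inline double runif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via the ziggurat method
  inline double rnorm() {
    int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(next()));
    uint32_t iz = static_cast<uint32_t>(hz) & 127;
    uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                          : static_cast<uint32_t>(hz);
    if (ahz < zig.kn[iz]) return hz * zig.wn[iz];
    return nfix(hz, iz);
  }

  double nfix(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    double x, y;
    for (;;) {
      x = hz * zig.wn[iz];
      if (iz == 0) { // base strip: sample the tail beyond r
        do {
          x = -std::log(runif()) / r;
          y = -std::log(runif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      if (zig.fn[iz] + runif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      hz = static_cast<int32_t>(static_cast<uint32_t>(next()));
      iz = static_cast<uint32_t>(hz) & 127;
      uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                            : static_cast<uint32_t>(hz);
      if (ahz < zig.kn[iz]) return hz * zig.wn[iz];
    }
  }
};

} // namespace

// Euler-Maruyama ensemble for the lumped secondary-neuron SDE
//   tau2 dx = (-x + scale * shape(t)) dt + sigma dW,  x(0) = 0,
// stepped as x_{m+1} = x_m + (dt/tau2) (scale*shape[m] - x_m)
//                    + (sigma/tau2) sqrt(dt) eta_m.
// `shape` holds the unit synaptic drive at t = 0, dt, ..., (M-1)*dt; the
// update towards x_{m+1} uses shape[m] (left endpoint). A path counts as a
// spike as soon as x >= alpha2 anywhere on the discrete grid; when paths are
// not returned the realization stops at the first crossing (the max-based
// response flag is unaffected).
//
// [[Rcpp::export]]
List cpp_ddm_ensemble(NumericVector shape, double scale, double tau2,
                      double sigma, double alpha2, double dt, int n,
                      int seed, int stream, bool return_paths = false,
                      int thin = 1) {
  const int M = shape.size();
  const double a = dt / tau2;
  const double b = (sigma / tau2) * std::sqrt(dt);
  const double keep = 1.0 - a;
  RngStream rng(seed, stream);

  // drift contribution of each step, precomputed once per ensemble
  std::vector<double> drive(M);
  for (int m = 0; m < M; ++m) drive[m] = a * scale * shape[m];

  IntegerVector crossed(n);
  NumericVector xmax(n);
  NumericMatrix paths;
  if (return_paths) {
    paths = NumericMatrix(n, M / thin + 1);
  }

  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    double xm = 0.0;
    bool hit = (0.0 >= alpha2);
    if (return_paths) {
      int col = 1;
      paths(i, 0) = 0.0;
      for (int m = 0; m < M; ++m) {
        x = keep * x + drive[m] + (b != 0.0 ? b * rng.rnorm() : 0.0);
        if (x > xm) xm = x;
        if ((m + 1) % thin == 0) paths(i, col++) = x;
      }
      if (xm >= alpha2) hit = true;
    } else if (b != 0.0) {
      // generate noise in blocks so the RNG pipeline and the (serial)
      // state-update chain do not stall each other
      const int B = 4096;
      static thread_local std::vector<double> nbuf;
      nbuf.resize(B);
      int pos = B;
      for (int m = 0; m < M; ++m) {
        if (pos == B) {
          const int fill = std::min(B, M - m);
          for (int j = 0; j < fill; ++j) nbuf[j] = b * rng.rnorm();
          pos = 0;
        }
        x = keep * x + drive[m] + nbuf[pos++];
        if (x > xm) xm = x;
        if (x >= alpha2) {
          hit = true;
          break;
        }
      }
    } else {
      for (int m = 0; m < M; ++m) {
        x = keep * x + drive[m];
        if (x > xm) xm = x;
        if (x >= alpha2) {
          hit = true;
          break;
        }
      }
    }
    crossed[i] = hit ? 1 : 0;
    xmax[i] = xm;
  }

  if (return_paths) {
    return List::create(_["crossed"] = crossed, _["xmax"] = xmax,
                        _["paths"] = paths);
  }
  return List::create(_["crossed"] = crossed, _["xmax"] = xmax);
}

// Raw draws from one stream, used to test the generator's distribution.
// [[Rcpp::export]]
NumericVector cpp_stream_normals(int n, int seed, int stream) {
  RngStream rng(seed, stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rnorm();
  return out;
}

// Uniform draws from one stream (used for reproducibility checks).
// [[Rcpp::export]]
NumericVector cpp_stream_uniforms(int n, int seed, int stream) {
  RngStream rng(seed, stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.runif();
  return out;
}
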