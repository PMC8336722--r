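// 2D voxel Monte Carlo photon transport with a track-length fluence
// estimator and continuous absorption weighting.
//
// Geometry: matrices are [nz, nx] with row 1 at the illuminated surface.
// x spans [-W/2, W/2] with W = nx*h; z spans [0, nz*h], increasing
// downward.  All lengths in mm, coefficients in 1/mm.
//
// Transport: free paths are sampled against mu_s; absorption attenuates the
// packet weight continuously along each sub-path, and the fluence tally in
// a voxel is the absorption-weighted path length (exact Beer-Lambert within
// a voxel).  Scattering angles follow the 2D Henyey-Greenstein phase
// function.  Packets are terminated when their weight drops below wmin;
// the dropped weight is tracked so that
//   deposited + escaped + dropped == launched
// holds to floating point round-off.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// deterministic across platforms: raw mt19937_64 draws, no std distributions
struct Rng {
  std::uint64_t s[2];
  explicit Rng(std::uint64_t seed) {
    // splitmix64 init
    std::uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      s[i] = t ^ (t >> 31);
    }
  }
  std::uint64_t next() { // xoroshiro128+
    std::uint64_t a = s[0], b = s[1];
    std::uint64_t r = a + b;
    b ^= a;
    s[0] = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s[1] = (b << 36) | (b >> 28);
    return r;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() { // Box-Muller (one value per call, cache the pair)
    if (has_) { has_ = false; return cached_; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached_ = r * std::sin(2.0 * M_PI * u2);
    has_ = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  bool has_ = false;
  double cached_ = 0.0;
};

} // namespace

// [[Rcpp::export]]
List mc_fluence_cpp(NumericMatrix mua, NumericMatrix musp, double g,
                    double h, double x0, double sigma, int n_photons,
                    int seed, double wmin) {
  const int nz = mua.nrow(), nx = mua.ncol();
  if (nz < 1 || nx < 1) stop("zero-size grid");
  if (n_photons < 1) stop("n_photons must be >= 1");
  const double W = nx * h, Zmax = nz * h;
  const double xlo = -W / 2.0;
  NumericMatrix flu(nz, nx);
  double deposited = 0.0, escaped = 0.0, dropped = 0.0;
  const double hg_fac = (1.0 - g) / (1.0 + g);
  Rng rng(static_cast<std::uint64_t>(seed));

  for (int p = 0; p < n_photons; ++p) {
    double x = x0 + (sigma > 0.0 ? sigma * rng.normal() : 0.0);
    double z = 0.0;
    if (x <= xlo || x >= xlo + W) { escaped += 1.0; continue; }
    double ux = 0.0, uz = 1.0, w = 1.0;
    int ix = static_cast<int>((x - xlo) / h);
    int iz = 0;
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    double tau = -std::log(rng.unif());
    bool alive = true;

    while (alive) {
      const double ms = musp(iz, ix) <= 0.0 ? 0.0
                        : musp(iz, ix) / (1.0 - g);
      const double ma = mua(iz, ix);
      // distance to the voxel boundary along the direction of flight
      double sx = std::numeric_limits<double>::infinity();
      double sz = std::numeric_limits<double>::infinity();
      if (ux > 0.0)      sx = ((ix + 1) * h + xlo - x) / ux;
      else if (ux < 0.0) sx = (ix * h + xlo - x) / ux;
      if (uz > 0.0)      sz = ((iz + 1) * h - z) / uz;
      else if (uz < 0.0) sz = (iz * h - z) / uz;
      double sb = sx < sz ? sx : sz;
      if (sb < 0.0) sb = 0.0;
      double ss = ms > 0.0 ? tau / ms
                           : std::numeric_limits<double>::infinity();
      const bool scatter_here = ss <= sb;
      const double s = scatter_here ? ss : sb;

      // deposit along the sub-path of length s
      if (ma > 0.0) {
        const double wend = w * std::exp(-ma * s);
        flu(iz, ix) += (w - wend) / ma;
        deposited += w - wend;
        w = wend;
      } else {
        flu(iz, ix) += w * s;
      }
      x += ux * s;
      z += uz * s;

      if (scatter_here) {
        double theta;
        if (g != 0.0) {
          theta = 2.0 * std::atan(hg_fac * std::tan(M_PI * (rng.unif() - 0.5)));
        } else {
          theta = 2.0 * M_PI * rng.unif();
        }
        const double ct = std::cos(theta), st = std::sin(theta);
        const double nux = ux * ct - uz * st;
        uz = ux * st + uz * ct;
        ux = nux;
        tau = -std::log(rng.unif());
      } else {
        tau -= ms * s;
        if (sx < sz) ix += (ux > 0.0) ? 1 : -1;
        else         iz += (uz > 0.0) ? 1 : -1;
        if (ix < 0 || ix >= nx || iz < 0 || iz >= nz) {
          escaped += w;
          alive = false;
        }
      }
      if (alive && w < wmin) {
        dropped += w;
        alive = false;
      }
    }
  }

  const double norm = static_cast<double>(n_photons) * h * h;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i)
      flu(i, j) /= norm;
  return List::create(_["fluence"] = flu,
                      _["deposited"] = deposited / n_photons,
                      _["escaped"] = escaped / n_photons,
                      _["dropped"] = dropped / n_photons);
}
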