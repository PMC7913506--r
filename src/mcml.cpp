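// Photon-packet Monte Carlo for steady-state diffuse reflectance of a
// layered turbid slab (hop-drop-spin rule set: exponential step sampling,
// weight drop mu_a/mu_t per interaction, Henyey-Greenstein deflection,
// Fresnel reflection/refraction at horizontal boundaries, Russian
// roulette). Only total diffuse reflectance/transmittance are tallied; no
// radial binning.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// deterministic 64-bit generator (xoshiro256**), seeded via splitmix64 so
// results are reproducible across platforms independent of R's RNG
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0,1]
  double unif_open0() { return 1.0 - unif(); }
};

struct Kahan {
  double sum = 0.0, c = 0.0;
  void add(double x) {
    double y = x - c;
    double t = sum + y;
    c = (t - sum) - y;
    sum = t;
  }
};

struct Layer {
  double z0, z1, mua, mus, g, n;
};

// unpolarized Fresnel reflectance; ca1 = |cos incident|, sets ca2
double fresnel(double ni, double nt, double ca1, double *ca2) {
  if (ni == nt) { *ca2 = ca1; return 0.0; }
  if (ca1 > 1.0 - 1e-12) {  // normal incidence
    *ca2 = ca1;
    double r = (nt - ni) / (nt + ni);
    return r * r;
  }
  if (ca1 < 1e-6) { *ca2 = 0.0; return 1.0; }  // grazing
  double sa1 = std::sqrt(1.0 - ca1 * ca1);
  double sa2 = ni * sa1 / nt;
  if (sa2 >= 1.0) { *ca2 = 0.0; return 1.0; }  // total internal reflection
  *ca2 = std::sqrt(1.0 - sa2 * sa2);
  double cap = ca1 * (*ca2) - sa1 * sa2;
  double cam = ca1 * (*ca2) + sa1 * sa2;
  double sap = sa1 * (*ca2) + ca1 * sa2;
  double sam = sa1 * (*ca2) - ca1 * sa2;
  return 0.5 * sam * sam * (cap * cap + cam * cam) / (sap * sap * cam * cam);
}

// Henyey-Greenstein scattering: update direction in place
void spin(double g, Rng &rng, double &ux, double &uy, double &uz) {
  double ct;
  if (g == 0.0) {
    ct = 2.0 * rng.unif() - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    ct = (1.0 + g * g - t * t) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 6.283185307179586476925286766559 * rng.unif();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    double uxn = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
    double uyn = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
    double uzn = -st * cp * tmp + uz * ct;
    ux = uxn; uy = uyn; uz = uzn;
  }
}

std::vector<Layer> build_layers(NumericVector thickness, NumericVector mua,
                                NumericVector mus, NumericVector g,
                                NumericVector n) {
  int L = thickness.size();
  if (L < 1) stop("at least one layer is required");
  if (mua.size() != L || mus.size() != L || g.size() != L || n.size() != L)
    stop("layer property vectors must share a common length");
  std::vector<Layer> layers(L);
  double z = 0.0;
  for (int i = 0; i < L; ++i) {
    if (!(thickness[i] > 0)) stop("layer thickness must be positive");
    if (mua[i] < 0 || mus[i] < 0) stop("mu_a and mu_s must be non-negative");
    if (!(g[i] > -1 && g[i] < 1)) stop("anisotropy g must lie in (-1, 1)");
    if (n[i] < 1) stop("refractive index must be >= 1");
    layers[i].z0 = z;
    z += thickness[i];
    layers[i].z1 = z;
    layers[i].mua = mua[i];
    layers[i].mus = mus[i];
    layers[i].g = g[i];
    layers[i].n = n[i];
  }
  return layers;
}

const long MAX_STEPS = 100000000L;  // hard safety per photon

}  // namespace

// [[Rcpp::export(name = ".mcml_run")]]
List mcml_run(NumericVector thickness, NumericVector mua, NumericVector mus,
              NumericVector g, NumericVector n, double n_ambient,
              double n_photons, double seed, double weight_threshold,
              double roulette_survival) {
  std::vector<Layer> layers =
      build_layers(thickness, mua, mus, g, n);
  int L = (int)layers.size();
  if (!(n_photons >= 1)) stop("n_photons must be >= 1");
  if (!(roulette_survival > 0 && roulette_survival < 1))
    stop("roulette_survival must lie in (0, 1)");
  if (!(weight_threshold > 0)) stop("weight_threshold must be positive");
  if (n_ambient < 1) stop("ambient refractive index must be >= 1");

  Rng rng((uint64_t)seed);
  long N = (long)n_photons;

  // specular reflection at entry (normal incidence)
  double r0 = (n_ambient - layers[0].n) / (n_ambient + layers[0].n);
  double rsp = r0 * r0;

  Kahan t_rd, t_td, t_abs, t_lost;
  for (long ip = 0; ip < N; ++ip) {
    double w = 1.0 - rsp;
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int il = 0;
    double sleft = 0.0;  // dimensionless optical path remaining
    bool alive = true;
    long steps = 0;
    while (alive) {
      if (++steps > MAX_STEPS) { t_lost.add(w); break; }
      Layer &ly = layers[il];
      double mut = ly.mua + ly.mus;
      if (sleft <= 0.0) sleft = -std::log(rng.unif_open0());
      // distance to the boundary ahead
      double db;
      if (uz > 0.0)      db = (ly.z1 - z) / uz;
      else if (uz < 0.0) db = (ly.z0 - z) / uz;
      else               db = 1e300;
      double dstep = (mut > 0.0) ? sleft / mut : 1e300;
      if (db <= dstep) {
        // hop to the boundary, then reflect or transmit
        z = (uz > 0.0) ? ly.z1 : ly.z0;
        if (mut > 0.0) sleft -= db * mut;
        bool down = uz > 0.0;
        double n_next = down ? (il + 1 < L ? layers[il + 1].n : n_ambient)
                             : (il > 0 ? layers[il - 1].n : n_ambient);
        double ca2;
        double R = fresnel(ly.n, n_next, std::fabs(uz), &ca2);
        if (rng.unif() < R) {
          uz = -uz;  // internal reflection
        } else {
          double scale = ly.n / n_next;
          ux *= scale; uy *= scale;
          uz = down ? ca2 : -ca2;
          if (down) {
            if (il + 1 < L) { ++il; }
            else { t_td.add(w); alive = false; }
          } else {
            if (il > 0) { --il; }
            else { t_rd.add(w); alive = false; }
          }
        }
      } else {
        // hop inside the layer, drop, spin
        z += uz * dstep;
        sleft = 0.0;
        double da = w * ly.mua / mut;
        w -= da;
        t_abs.add(da);
        if (w < weight_threshold) {
          // Russian roulette: unbiased net bookkeeping of removed weight
          if (rng.unif() < roulette_survival) {
            double w_new = w / roulette_survival;
            t_lost.add(w - w_new);
            w = w_new;
          } else {
            t_lost.add(w);
            alive = false;
            break;
          }
        }
        spin(ly.g, rng, ux, uy, uz);
      }
    }
  }

  double inv = 1.0 / (double)N;
  return List::create(
      _["r_specular"] = rsp,
      _["r_diffuse"] = t_rd.sum * inv,
      _["t_diffuse"] = t_td.sum * inv,
      _["absorbed"] = t_abs.sum * inv,
      _["lost_roulette"] = t_lost.sum * inv,
      _["n_photons"] = (double)N);
}

// Null-absorption trajectory library: photons propagate with mu_a = 0 and
// the geometric path length accumulated in every layer is recorded for
// each packet that escapes through the top surface. Diffuse reflectance
// for arbitrary per-layer absorption is then the expectation of
// exp(-sum_l mu_a[l] * L[l]) (continuous absorption weighting), which is
// an unbiased estimator of the analog random walk.
// [[Rcpp::export(name = ".mcml_pathlengths")]]
List mcml_pathlengths(NumericVector thickness, NumericVector mus,
                      NumericVector g, NumericVector n, double n_ambient,
                      double n_photons, double seed) {
  NumericVector mua0(thickness.size(), 0.0);
  std::vector<Layer> layers = build_layers(thickness, mua0, mus, g, n);
  int L = (int)layers.size();
  if (!(n_photons >= 1)) stop("n_photons must be >= 1");
  if (n_ambient < 1) stop("ambient refractive index must be >= 1");
  for (int i = 0; i < L; ++i)
    if (!(layers[i].mus > 0))
      stop("path-length mode requires mu_s > 0 in every layer");

  Rng rng((uint64_t)seed);
  long N = (long)n_photons;
  double r0 = (n_ambient - layers[0].n) / (n_ambient + layers[0].n);
  double rsp = r0 * r0;

  std::vector<double> ltop;    // row-major n_top x L
  ltop.reserve((size_t)(N / 2) * L);
  long n_top = 0, n_bottom = 0, n_lost = 0;
  std::vector<double> len(L);

  for (long ip = 0; ip < N; ++ip) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int il = 0;
    double sleft = 0.0;
    std::fill(len.begin(), len.end(), 0.0);
    long steps = 0;
    int fate = -1;  // 0 top, 1 bottom, 2 lost
    while (fate < 0) {
      if (++steps > MAX_STEPS) { fate = 2; break; }
      Layer &ly = layers[il];
      double mut = ly.mus;
      if (sleft <= 0.0) sleft = -std::log(rng.unif_open0());
      double db;
      if (uz > 0.0)      db = (ly.z1 - z) / uz;
      else if (uz < 0.0) db = (ly.z0 - z) / uz;
      else               db = 1e300;
      double dstep = sleft / mut;
      if (db <= dstep) {
        z = (uz > 0.0) ? ly.z1 : ly.z0;
        sleft -= db * mut;
        len[il] += db;
        bool down = uz > 0.0;
        double n_next = down ? (il + 1 < L ? layers[il + 1].n : n_ambient)
                             : (il > 0 ? layers[il - 1].n : n_ambient);
        double ca2;
        double R = fresnel(ly.n, n_next, std::fabs(uz), &ca2);
        if (rng.unif() < R) {
          uz = -uz;
        } else {
          double scale = ly.n / n_next;
          ux *= scale; uy *= scale;
          uz = down ? ca2 : -ca2;
          if (down) { if (il + 1 < L) ++il; else fate = 1; }
          else      { if (il > 0) --il; else fate = 0; }
        }
      } else {
        z += uz * dstep;
        len[il] += dstep;
        sleft = 0.0;
        spin(ly.g, rng, ux, uy, uz);
      }
    }
    if (fate == 0) {
      for (int i = 0; i < L; ++i) ltop.push_back(len[i]);
      ++n_top;
    } else if (fate == 1) {
      ++n_bottom;
    } else {
      ++n_lost;
    }
  }

  NumericMatrix Lmat(n_top, L);
  for (long r = 0; r < n_top; ++r)
    for (int c = 0; c < L; ++c)
      Lmat(r, c) = ltop[(size_t)r * L + c];

  return List::create(
      _["lengths_top"] = Lmat,
      _["n_top"] = (double)n_top,
      _["n_bottom"] = (double)n_bottom,
      _["n_lost"] = (double)n_lost,
      _["r_specular"] = rsp,
      _["n_photons"] = (double)N);
}
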