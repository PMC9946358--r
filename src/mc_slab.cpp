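#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Counter-free xoshiro256++ generator seeded through splitmix64 so that a
// single integer seed fully determines every tally (reproducibility contract).
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
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
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Unpolarized Fresnel power reflectance for a ray hitting an n1 -> n2
// interface with incidence cosine cosi (> 0). Returns 1 beyond the critical
// angle when n1 > n2.
inline double fresnel_R(double n1, double n2, double cosi) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  double sini2 = 1.0 - cosi * cosi;
  if (sini2 < 0.0) sini2 = 0.0;
  double sint = n1 / n2 * std::sqrt(sini2);
  if (sint >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by inverse CDF.
inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-9) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

}  // namespace

// Weighted-photon MCML-style transport through a plane-parallel slab with the
// same ambient index on both faces. Lengths in mm, depths sorted ascending.
// [[Rcpp::export]]
List mc_slab_cpp(double mu_a, double mu_s, double g, double n_sample,
                 double thickness, double n_ambient, double n_photons_d,
                 double seed_d, double angular_bin_deg, NumericVector depths_mm,
                 double pitch_mm, int half_cells, double roulette_threshold,
                 double roulette_survival, int n_batches) {
  const long long n_photons = (long long)n_photons_d;
  const double mu_t = mu_a + mu_s;
  const int n_bins = (int)std::ceil(90.0 / angular_bin_deg);
  const int ndep = depths_mm.size();
  const int side = 2 * half_cells + 1;

  Xoshiro rng((uint64_t)seed_d);

  double Tw = 0.0, Rw = 0.0, Rspecw = 0.0, Aw = 0.0;
  std::vector<double> ang(n_bins, 0.0);
  std::vector<double> batchT(n_batches, 0.0), batchR(n_batches, 0.0);
  std::vector<double> batch_n(n_batches, 0.0);
  std::vector<double> psf;
  std::vector<double> psf_lost;
  if (ndep > 0) {
    psf.assign((size_t)side * side * ndep, 0.0);
    psf_lost.assign(ndep, 0.0);
  }

  const double Rsp_entry = fresnel_R(n_ambient, n_sample, 1.0);
  const double deg = 180.0 / M_PI;

  long long base = n_photons / n_batches, rem = n_photons % n_batches;
  for (int b = 0; b < n_batches; ++b) {
    long long nb_ph = base + (b < rem ? 1 : 0);
    batch_n[b] = (double)nb_ph;
    for (long long ph = 0; ph < nb_ph; ++ph) {
      double w = 1.0, x = 0.0, y = 0.0, z = 0.0;
      double ux = 0.0, uy = 0.0, uz = 1.0;

      if (Rsp_entry > 0.0 && rng.unif() < Rsp_entry) {
        Rw += 1.0;
        Rspecw += 1.0;
        batchR[b] += 1.0;
        continue;
      }

      bool alive = true;
      while (alive) {
        double s = (mu_t > 0.0) ? -std::log(1.0 - rng.unif()) / mu_t : 1e30;
        while (alive && s > 0.0) {
          double db;
          if (uz > 1e-12)
            db = (thickness - z) / uz;
          else if (uz < -1e-12)
            db = -z / uz;
          else
            db = 1e30;
          const double step = (db <= s) ? db : s;

          // Depth-plane PSF tally: weight at each downward crossing.
          if (ndep > 0 && uz > 0.0) {
            const double z1 = z + uz * step;
            for (int k = 0; k < ndep; ++k) {
              const double zk = depths_mm[k];
              if (zk > z && zk <= z1) {
                const double t = (zk - z) / uz;
                const long ix = (long)std::lround((x + ux * t) / pitch_mm);
                const long iy = (long)std::lround((y + uy * t) / pitch_mm);
                if (ix >= -half_cells && ix <= half_cells &&
                    iy >= -half_cells && iy <= half_cells) {
                  psf[(size_t)k * side * side +
                      (size_t)(iy + half_cells) * side + (ix + half_cells)] +=
                      w;
                } else {
                  psf_lost[k] += w;
                }
              }
            }
          }

          x += ux * step;
          y += uy * step;
          z += uz * step;

          if (db <= s) {
            // Boundary hit before the sampled interaction point.
            s -= db;
            const bool bottom = (uz > 0.0);
            z = bottom ? thickness : 0.0;
            const double cosi = std::fabs(uz);
            const double Rf = fresnel_R(n_sample, n_ambient, cosi);
            if (rng.unif() < Rf) {
              uz = -uz;  // internal reflection, spend the remaining path
            } else {
              // Escape: refract the exit direction into the ambient medium.
              double sini2 = 1.0 - cosi * cosi;
              if (sini2 < 0.0) sini2 = 0.0;
              const double sint = n_sample / n_ambient * std::sqrt(sini2);
              double cost2 = 1.0 - sint * sint;
              if (cost2 < 0.0) cost2 = 0.0;
              const double cost = std::sqrt(cost2);
              if (bottom) {
                Tw += w;
                batchT[b] += w;
                const double theta_deg = std::acos(cost) * deg;
                int bin = (int)(theta_deg / angular_bin_deg);
                if (bin >= n_bins) bin = n_bins - 1;
                ang[bin] += w;
              } else {
                Rw += w;
                batchR[b] += w;
              }
              alive = false;
            }
          } else {
            s = 0.0;  // interaction site reached
          }
        }
        if (!alive || mu_t <= 0.0) break;

        // Interaction: deposit the absorbed fraction, then scatter.
        if (mu_a > 0.0) {
          const double da = w * mu_a / mu_t;
          Aw += da;
          w -= da;
        }
        const double ct = hg_cos(g, rng.unif());
        const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * rng.unif();
        const double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 1.0 - 1e-6) {
          ux = st * cp;
          uy = st * sp;
          uz = (uz >= 0.0) ? ct : -ct;
        } else {
          const double denom = std::sqrt(1.0 - uz * uz);
          const double nux = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
          const double nuy = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
          const double nuz = -st * cp * denom + uz * ct;
          ux = nux;
          uy = nuy;
          uz = nuz;
        }
        const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm;
        uy /= nrm;
        uz /= nrm;

        if (w < roulette_threshold) {
          if (rng.unif() < roulette_survival)
            w /= roulette_survival;
          else
            alive = false;
        }
      }
    }
  }

  NumericVector angv(ang.begin(), ang.end());
  NumericVector bT(n_batches), bR(n_batches);
  for (int b = 0; b < n_batches; ++b) {
    bT[b] = batchT[b] / batch_n[b];
    bR[b] = batchR[b] / batch_n[b];
  }

  List out = List::create(
      _["T_total"] = Tw / n_photons, _["R_total"] = Rw / n_photons,
      _["R_specular"] = Rspecw / n_photons, _["A_total"] = Aw / n_photons,
      _["ang_weight"] = angv, _["batch_T"] = bT, _["batch_R"] = bR);
  if (ndep > 0) {
    NumericVector cube(psf.begin(), psf.end());
    cube.attr("dim") = IntegerVector::create(side, side, ndep);
    out["psf"] = cube;
    out["psf_lost"] = NumericVector(psf_lost.begin(), psf_lost.end());
  }
  return out;
}
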