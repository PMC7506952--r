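#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Self-contained counter-free PRNG (splitmix64 seeding + xoshiro256++)
// so that simulations are bit-identical for a given seed regardless of
// R's RNG kind or state, on any platform with IEEE doubles.

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
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

  // uniform in (0, 1]; never 0 so -log(u) is finite
  double runif_pos() {
    return (static_cast<double>(next() >> 11) + 1.0) * 0x1.0p-53;
  }
  // uniform in [0, 1)
  double runif() {
    return static_cast<double>(next() >> 11) * 0x1.0p-53;
  }
};

double fresnel_R(double n1, double n2, double cosi) {
  if (n1 == n2) return 0.0;
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (n1 / n2) * (n1 / n2) * sini2;
  if (sint2 >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by inverse-CDF
double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

struct Photon {
  double x, y, z;
  double ux, uy, uz;
  double w;
  int layer;      // 1 = front wall, 2 = suspension, 3 = rear wall
  long nscat;
};

// Rotate direction by polar angle (cost) and azimuth (phi): MCML convention.
void spin(Photon &p, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  if (std::fabs(uz) > 0.99999) {
    p.ux = sint * cosp;
    p.uy = sint * sinp;
    p.uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    p.ux = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
    p.uy = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
    p.uz = -sint * cosp * tmp + uz * cost;
  }
  double norm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= norm; p.uy /= norm; p.uz /= norm;
}

}  // namespace

// Monte-Carlo photon transport through an air | wall | suspension | wall | air
// slab stack (normal-incidence pencil beam along +z, z = 0 at the front
// air|wall interface). Weighted photons with implicit capture; Russian
// roulette whose kill/boost ledger is folded into the medium-absorption tally
// (zero expectation), keeping the per-run weight ledger exact.
// [[Rcpp::export]]
Rcpp::List mc_cuvette_cpp(double mu_a, double mu_s, double g,
                          double wall_thickness, double suspension_thickness,
                          double n_outside, double n_wall, double n_suspension,
                          double half_width, double accept_cos,
                          double n_photons_d, double weight_threshold,
                          double roulette_survival, double seed_d) {
  const long n_photons = static_cast<long>(n_photons_d);
  Xoshiro256 rng(static_cast<uint64_t>(seed_d));

  const double z0 = 0.0;
  const double z1 = wall_thickness;
  const double z2 = wall_thickness + suspension_thickness;
  const double z3 = 2.0 * wall_thickness + suspension_thickness;
  const double mu_t = mu_a + mu_s;
  const double albedo = (mu_t > 0.0) ? mu_s / mu_t : 1.0;

  // tallies and per-photon second moments for the exit channels
  double t_c = 0, t_d = 0, r_d = 0, a_med = 0, side = 0;
  double t_c2 = 0, t_d2 = 0, r_d2 = 0;

  for (long i = 0; i < n_photons; ++i) {
    Photon p{0, 0, 0, 0, 0, 1.0, 1, 1, 0};
    double exit_tc = 0, exit_td = 0, exit_rd = 0;

    // entry interface air | front wall
    if (rng.runif() < fresnel_R(n_outside, n_wall, 1.0)) {
      r_d += p.w; r_d2 += p.w * p.w;
      continue;
    }
    bool alive = true;
    while (alive) {
      // boundaries of the current layer
      double zlo, zhi, n_here;
      if (p.layer == 1)      { zlo = z0; zhi = z1; n_here = n_wall; }
      else if (p.layer == 2) { zlo = z1; zhi = z2; n_here = n_suspension; }
      else                   { zlo = z2; zhi = z3; n_here = n_wall; }

      bool interacting = (p.layer == 2) && (mu_t > 0.0);
      double db;  // distance to layer boundary along flight
      if (p.uz > 0)      db = (zhi - p.z) / p.uz;
      else if (p.uz < 0) db = (zlo - p.z) / p.uz;
      else               db = 1e30;

      double s = interacting ? -std::log(rng.runif_pos()) / mu_t : 1e30;

      if (s < db) {
        // interaction inside the suspension
        p.x += s * p.ux; p.y += s * p.uy; p.z += s * p.uz;
        if (std::fabs(p.x) > half_width || std::fabs(p.y) > half_width) {
          side += p.w;
          break;
        }
        double dep = p.w * (1.0 - albedo);
        a_med += dep;
        p.w -= dep;
        double cost = hg_cos(g, rng.runif());
        double phi = 2.0 * M_PI * rng.runif();
        spin(p, cost, phi);
        p.nscat += 1;
        if (p.w < weight_threshold) {
          if (rng.runif() < roulette_survival) {
            double boost = p.w / roulette_survival - p.w;
            a_med -= boost;           // ledger: weight created by roulette
            p.w += boost;
          } else {
            a_med += p.w;             // ledger: weight destroyed by roulette
            break;
          }
        }
      } else {
        // propagate to the layer boundary and resolve the interface
        p.x += db * p.ux; p.y += db * p.uy;
        p.z = (p.uz > 0) ? zhi : zlo;
        if (std::fabs(p.x) > half_width || std::fabs(p.y) > half_width) {
          side += p.w;
          break;
        }
        double n_next;
        int next_layer;
        bool exits_front = false, exits_rear = false;
        if (p.uz > 0) {
          if (p.layer == 1)      { n_next = n_suspension; next_layer = 2; }
          else if (p.layer == 2) { n_next = n_wall;       next_layer = 3; }
          else                   { n_next = n_outside;    next_layer = 4; exits_rear = true; }
        } else {
          if (p.layer == 3)      { n_next = n_suspension; next_layer = 2; }
          else if (p.layer == 2) { n_next = n_wall;       next_layer = 1; }
          else                   { n_next = n_outside;    next_layer = 0; exits_front = true; }
        }
        double cosi = std::fabs(p.uz);
        double R = fresnel_R(n_here, n_next, cosi);
        if (rng.runif() < R) {
          p.uz = -p.uz;  // specular reflection, stay in layer
        } else {
          // refract (Snell)
          double ratio = n_here / n_next;
          double sint2 = ratio * ratio * (1.0 - cosi * cosi);
          double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
          p.ux *= ratio; p.uy *= ratio;
          p.uz = (p.uz > 0) ? cost : -cost;
          if (exits_rear) {
            if (p.nscat == 0 && cost >= accept_cos) { exit_tc = p.w; t_c += p.w; }
            else { exit_td = p.w; t_d += p.w; }
            alive = false;
          } else if (exits_front) {
            exit_rd = p.w; r_d += p.w;
            alive = false;
          } else {
            p.layer = next_layer;
          }
        }
      }
    }
    t_c2 += exit_tc * exit_tc;
    t_d2 += exit_td * exit_td;
    r_d2 += exit_rd * exit_rd;
  }

  const double n = static_cast<double>(n_photons);
  auto se = [n](double sum, double sumsq) {
    double m = sum / n;
    double v = sumsq / n - m * m;
    if (v < 0) v = 0;
    return std::sqrt(v / n);
  };

  return Rcpp::List::create(
    Rcpp::Named("T_C") = t_c / n,
    Rcpp::Named("T_D") = t_d / n,
    Rcpp::Named("R_D") = r_d / n,
    Rcpp::Named("A_medium") = a_med / n,
    Rcpp::Named("side_loss") = side / n,
    Rcpp::Named("se_T_C") = se(t_c, t_c2),
    Rcpp::Named("se_T_D") = se(t_d, t_d2),
    Rcpp::Named("se_R_D") = se(r_d, r_d2));
}
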