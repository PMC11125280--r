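#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted-photon random walk through a z-layered medium, depositing
// absorbed weight on a Cartesian voxel grid. Hop/drop/spin with
// Henyey-Greenstein deflection, unpolarized Fresnel reflection/refraction
// at layer interfaces, and Russian-roulette termination. Uses R's RNG so
// runs are reproducible under set.seed().

static const double EPS = 1e-12;

static inline double rnd() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// standard direction update after scattering by (cost, phi)
static inline void spin(double &ux, double &uy, double &uz,
                        double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    double nux = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
    double nuy = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
    double nuz = -sint * cosp * tmp + uz * cost;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

static inline double hg_cost(double g) {
  if (std::fabs(g) < 1e-6) return 2.0 * rnd() - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rnd());
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  return std::max(-1.0, std::min(1.0, c));
}

// [[Rcpp::export]]
List mc_transport(IntegerVector nvox, double pitch,
                  NumericVector mu_a, NumericVector mu_s,
                  NumericVector g, NumericVector nrefr,
                  NumericVector zbounds,
                  NumericMatrix pos0, NumericMatrix dir0, NumericVector w0,
                  double w_threshold, double rr_survive) {
  const int nx = nvox[0], ny = nvox[1], nz = nvox[2];
  const double ex = nx * pitch, ey = ny * pitch, ez = nz * pitch;
  const int nlayer = mu_a.size();
  const int nph = pos0.nrow();
  NumericVector absorbed((R_xlen_t)nx * ny * nz);

  double launched = 0, absorbed_total = 0, escaped_total = 0;
  double rr_created = 0, rr_destroyed = 0;
  const long max_events = 1000000L;

  for (int p = 0; p < nph; ++p) {
    double x = pos0(p, 0), y = pos0(p, 1), z = pos0(p, 2);
    double ux = dir0(p, 0), uy = dir0(p, 1), uz = dir0(p, 2);
    double w = w0[p];
    launched += w;

    // snap launch positions that sit on the cube faces to within the grid
    if (z < 0 && z > -1e-9) z = 0;
    if (z >= ez && z < ez + 1e-9) z = ez * (1.0 - 1e-12);

    // locate the current layer from z
    int layer = 0;
    while (layer < nlayer - 1 && z >= zbounds[layer + 1]) ++layer;
    if (z < zbounds[0] || z >= zbounds[nlayer]) { escaped_total += w; continue; }

    bool alive = true;
    long events = 0;
    while (alive && ++events < max_events) {
      double mt = mu_a[layer] + mu_s[layer];
      double s = -std::log(rnd()); // dimensionless step
      // hop, possibly through several layer boundaries
      bool interacted = false;
      while (alive) {
        double dfree = (mt > 0) ? s / mt : R_PosInf;
        double db;
        if (uz > EPS) db = (zbounds[layer + 1] - z) / uz;
        else if (uz < -EPS) db = (zbounds[layer] - z) / uz;
        else db = R_PosInf;
        if (db < 0) db = 0;
        double d = std::min(dfree, db);
        x += ux * d; y += uy * d; z += uz * d;
        if (x < 0 || x >= ex || y < 0 || y >= ey) {
          escaped_total += w; alive = false; break;
        }
        if (dfree <= db) { interacted = (mt > 0); s = 0; break; }
        // boundary hit
        s -= db * mt;
        int next = layer + (uz > 0 ? 1 : -1);
        if (next < 0 || next >= nlayer) { // leaves the cube top/bottom
          escaped_total += w; alive = false; break;
        }
        double n1 = nrefr[layer], n2 = nrefr[next];
        // snap onto the boundary plane
        z = (uz > 0) ? zbounds[layer + 1] : zbounds[layer];
        if (std::fabs(n1 - n2) > 1e-9) {
          double ci = std::fabs(uz);
          double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
          double st = n1 / n2 * si;
          if (st >= 1.0) {
            uz = -uz; // total internal reflection
          } else {
            double ct = std::sqrt(1.0 - st * st);
            double Rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
            double Rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
            double R = 0.5 * (Rs * Rs + Rp * Rp);
            if (rnd() < R) {
              uz = -uz;
            } else {
              double scale = n1 / n2;
              ux *= scale; uy *= scale;
              uz = (uz > 0 ? ct : -ct);
              double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= norm; uy /= norm; uz /= norm;
              layer = next;
            }
          }
        } else {
          layer = next;
        }
        // nudge off the boundary so the next db is computed in-layer
        z += uz * EPS;
        mt = mu_a[layer] + mu_s[layer];
      }
      if (!alive) break;
      if (!interacted) continue;

      // drop: partial-weight absorption into the local voxel
      double dw = w * mu_a[layer] / mt;
      if (dw > 0 && z >= 0 && z < ez) {
        int ix = (int)(x / pitch), iy = (int)(y / pitch), iz = (int)(z / pitch);
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
          absorbed[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] += dw;
        absorbed_total += dw;
        w -= dw;
      }
      if (w <= 0) break; // fully absorbed (pure absorber)

      // spin
      spin(ux, uy, uz, hg_cost(g[layer]), 2.0 * M_PI * rnd());

      // Russian roulette
      if (w < w_threshold) {
        if (rnd() < rr_survive) {
          rr_created += w * (1.0 / rr_survive - 1.0);
          w /= rr_survive;
        } else {
          rr_destroyed += w;
          alive = false;
        }
      }
    }
    // event-cap safety: book any remaining weight so the ledger stays exact
    if (alive && events >= max_events && w > 0) escaped_total += w;
  }

  return List::create(
    _["absorbed"] = absorbed,
    _["launched"] = launched,
    _["absorbed_total"] = absorbed_total,
    _["escaped_total"] = escaped_total,
    _["rr_created"] = rr_created,
    _["rr_destroyed"] = rr_destroyed);
}
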