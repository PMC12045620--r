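// Compiled core: overdamped Brownian-dynamics integration of dipolar active
// Brownian particles among circular obstacles and plane walls, plus a local
// thickness painter for the water-gap granulometry.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-style RNG: one splitmix64-seeded xoshiro256+ stream per simulation.
// R's RNG is far too slow for the ~1e9 normal draws of a channel run.
namespace rng {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {  // Box-Muller, cached pair
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace rng

// ---------------------------------------------------------------------------
// Geometry support

struct Walls {
  std::vector<double> nx, ny, c;
  size_t size() const { return nx.size(); }
};

// Cell list over obstacles: each cell holds indices of circles whose surface
// (expanded by `skin`) can be reached from inside the cell.
struct ObstacleGrid {
  const std::vector<double> &ox, &oy, &orr;
  double skin, cell, x0, y0;
  int ncx = 0, ncy = 0;
  bool use_grid = false;
  std::vector<std::vector<int> > cells;

  ObstacleGrid(const std::vector<double> &ox_, const std::vector<double> &oy_,
               const std::vector<double> &or_, double skin_)
      : ox(ox_), oy(oy_), orr(or_), skin(skin_), cell(25.0), x0(0), y0(0) {
    size_t n = ox.size();
    if (n <= 16) return;  // brute force is cheaper for trap geometries
    double maxr = 0, xlo = 1e300, xhi = -1e300, ylo = 1e300, yhi = -1e300;
    for (size_t i = 0; i < n; ++i) {
      maxr = std::max(maxr, orr[i]);
      xlo = std::min(xlo, ox[i]); xhi = std::max(xhi, ox[i]);
      ylo = std::min(ylo, oy[i]); yhi = std::max(yhi, oy[i]);
    }
    double m = maxr + skin + 2.0;
    x0 = xlo - m; y0 = ylo - m;
    ncx = (int)std::ceil((xhi + m - x0) / cell) + 1;
    ncy = (int)std::ceil((yhi + m - y0) / cell) + 1;
    cells.assign((size_t)ncx * ncy, std::vector<int>());
    for (size_t i = 0; i < n; ++i) {
      double re = orr[i] + skin;
      int cx0 = std::max(0, (int)std::floor((ox[i] - re - x0) / cell));
      int cx1 = std::min(ncx - 1, (int)std::floor((ox[i] + re - x0) / cell));
      int cy0 = std::max(0, (int)std::floor((oy[i] - re - y0) / cell));
      int cy1 = std::min(ncy - 1, (int)std::floor((oy[i] + re - y0) / cell));
      for (int cx = cx0; cx <= cx1; ++cx)
        for (int cy = cy0; cy <= cy1; ++cy) {
          // rect-circle intersection test
          double qx = std::min(std::max(ox[i], x0 + cx * cell), x0 + (cx + 1) * cell);
          double qy = std::min(std::max(oy[i], y0 + cy * cell), y0 + (cy + 1) * cell);
          double dx = ox[i] - qx, dy = oy[i] - qy;
          if (dx * dx + dy * dy <= re * re)
            cells[(size_t)cx * ncy + cy].push_back((int)i);
        }
    }
    use_grid = true;
  }

  // nearest obstacle with surface within `skin`; returns index or -1.
  // h_out is the centre-to-surface distance of that obstacle (valid if >= 0
  // index), or +inf when none is in range.
  inline int nearest(double x, double y, double &h_out,
                     double &nx_, double &ny_) const {
    double best = skin;
    int best_i = -1;
    if (!use_grid) {
      for (size_t i = 0; i < ox.size(); ++i) {
        double dx = x - ox[i], dy = y - oy[i];
        double d = std::sqrt(dx * dx + dy * dy);
        double h = d - orr[i];
        if (h < best) { best = h; best_i = (int)i; nx_ = dx / d; ny_ = dy / d; }
      }
    } else {
      int cx = (int)std::floor((x - x0) / cell);
      int cy = (int)std::floor((y - y0) / cell);
      if (cx >= 0 && cx < ncx && cy >= 0 && cy < ncy) {
        const std::vector<int> &cand = cells[(size_t)cx * ncy + cy];
        for (size_t k = 0; k < cand.size(); ++k) {
          int i = cand[k];
          double dx = x - ox[i], dy = y - oy[i];
          double d = std::sqrt(dx * dx + dy * dy);
          double h = d - orr[i];
          if (h < best) { best = h; best_i = i; nx_ = dx / d; ny_ = dy / d; }
        }
      }
    }
    h_out = (best_i >= 0) ? best : 1e300;
    return best_i;
  }

  // accumulate WCA force over every obstacle whose surface is within the
  // cutoff; returns the number of contacts and the minimal h
  template <class F>
  inline void for_candidates(double x, double y, F f) const {
    if (!use_grid) {
      for (size_t i = 0; i < ox.size(); ++i) f((int)i);
    } else {
      int cx = (int)std::floor((x - x0) / cell);
      int cy = (int)std::floor((y - y0) / cell);
      if (cx < 0 || cx >= ncx || cy < 0 || cy >= ncy) return;
      const std::vector<int> &cand = cells[(size_t)cx * ncy + cy];
      for (size_t k = 0; k < cand.size(); ++k) f(cand[k]);
    }
  }

  inline bool inside_any(double x, double y) const {
    if (!use_grid) {
      for (size_t i = 0; i < ox.size(); ++i) {
        double dx = x - ox[i], dy = y - oy[i];
        if (dx * dx + dy * dy < orr[i] * orr[i]) return true;
      }
      return false;
    }
    int cx = (int)std::floor((x - x0) / cell);
    int cy = (int)std::floor((y - y0) / cell);
    if (cx < 0 || cx >= ncx || cy < 0 || cy >= ncy) return false;
    const std::vector<int> &cand = cells[(size_t)cx * ncy + cy];
    for (size_t k = 0; k < cand.size(); ++k) {
      int i = cand[k];
      double dx = x - ox[i], dy = y - oy[i];
      if (dx * dx + dy * dy < orr[i] * orr[i]) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".abp_run_cpp")]]
List abp_run_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                 NumericVector obs_x, NumericVector obs_y, NumericVector obs_r,
                 NumericMatrix walls,
                 double sigma, double v0, double eps_J, double mu,
                 double alpha_um, double gammaT, double gammaR,
                 double DT, double DR,
                 NumericVector field_t, NumericVector field_B,
                 double dt, double duration, double sample_interval,
                 double seed, int stop_mode, double x_stop,
                 double stop_cx, double stop_cy,
                 bool record_frames, bool all_contacts) {
  const int n = x0.size();
  const double cutoff = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double band = cutoff - 0.5 * sigma;       // interaction band (h)
  const double stiff_h = 0.45 * sigma;            // fine-step trigger
  const double max_disp = 0.02;                   // um per elementary step
  const double skin = 3.0;                        // um, contact search range

  std::vector<double> ox(obs_x.begin(), obs_x.end());
  std::vector<double> oy(obs_y.begin(), obs_y.end());
  std::vector<double> orr(obs_r.begin(), obs_r.end());
  ObstacleGrid grid(ox, oy, orr, skin);

  Walls W;
  for (int k = 0; k < walls.nrow(); ++k) {
    W.nx.push_back(walls(k, 0));
    W.ny.push_back(walls(k, 1));
    W.c.push_back(walls(k, 2));
  }

  rng::Xoshiro R((uint64_t)seed);

  std::vector<double> px(x0.begin(), x0.end());
  std::vector<double> py(y0.begin(), y0.end());
  std::vector<double> pphi(phi0.begin(), phi0.end());
  std::vector<char> active(n, 1);
  std::vector<double> stop_time(n, NA_REAL);
  int n_active = n;
  long long n_reject = 0;
  double min_h_seen = 1e300;

  const long long nsteps = (duration > 0) ? (long long)std::llround(duration / dt) : 0;
  long long sample_every = 1;
  int nframes = 1;
  if (record_frames) {
    sample_every = std::max(1LL, (long long)std::llround(sample_interval / dt));
    nframes = 1 + (int)(nsteps / sample_every);
  }
  NumericMatrix FX(record_frames ? n : 0, record_frames ? nframes : 0);
  NumericMatrix FY(record_frames ? n : 0, record_frames ? nframes : 0);
  NumericMatrix FPHI(record_frames ? n : 0, record_frames ? nframes : 0);
  NumericVector frame_t(record_frames ? nframes : 0);
  if (record_frames) {
    for (int i = 0; i < n; ++i) {
      FX(i, 0) = px[i]; FY(i, 0) = py[i]; FPHI(i, 0) = pphi[i];
    }
    frame_t[0] = 0.0;
  }

  // field schedule lookup (piecewise constant, field_t[0] == 0)
  int fseg = 0;
  const int nseg = field_t.size();
  const double two_pi = 6.283185307179586476925286766559;
  const double vF_scale = 1e6 / gammaT;    // N -> um/s
  const double tauS_scale = alpha_um * 1e-6 / gammaR;  // (N) x um lever -> rad/s

  for (long long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    while (fseg + 1 < nseg && t >= field_t[fseg + 1]) ++fseg;
    const double B = field_B[fseg];
    const double rateB = mu * B / gammaR;  // rad/s prefactor of -sin(phi)

    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double remaining = dt;
      int guard = 0;
      while (remaining > 0.0) {
        if (++guard > 200000) stop("sub-stepping failed to converge");
        double x = px[i], y = py[i], phi = pphi[i];

        // nearest solid element: obstacles first, then walls (ties -> obstacle)
        double h_obs, nx = 0, ny = 0;
        int io = grid.nearest(x, y, h_obs, nx, ny);
        double h = h_obs;
        bool wall_contact = false;
        double wnx = 0, wny = 0;
        for (size_t k = 0; k < W.size(); ++k) {
          double hw = W.nx[k] * x + W.ny[k] * y - W.c[k];
          if (hw < h) { h = hw; wall_contact = true; wnx = W.nx[k]; wny = W.ny[k]; }
        }
        if (h < min_h_seen) min_h_seen = h;
        if (wall_contact) { nx = wnx; ny = wny; }

        double Fx = 0, Fy = 0;
        if (!all_contacts) {
          // WCA force from the single nearest contact
          if ((io >= 0 || wall_contact) && h + 0.5 * sigma < cutoff) {
            double rs = h + 0.5 * sigma;
            if (rs < 0.05 * sigma) rs = 0.05 * sigma;
            double s2 = (sigma / rs) * (sigma / rs);
            double s6 = s2 * s2 * s2;
            double fmag = 48.0 * eps_J / (rs * 1e-6) * (s6 * s6 - 0.5 * s6);
            Fx = fmag * nx; Fy = fmag * ny;
          }
        } else if (h + 0.5 * sigma < cutoff) {
          // every solid element within the cutoff contributes its own
          // virtual-particle force (wedge apices: both pillars push)
          grid.for_candidates(x, y, [&](int i) {
            double dx = x - grid.ox[i], dy = y - grid.oy[i];
            double d = std::sqrt(dx * dx + dy * dy);
            double rs = d - grid.orr[i] + 0.5 * sigma;
            if (rs >= cutoff) return;
            if (rs < 0.05 * sigma) rs = 0.05 * sigma;
            double s2 = (sigma / rs) * (sigma / rs);
            double s6 = s2 * s2 * s2;
            double fmag = 48.0 * eps_J / (rs * 1e-6) * (s6 * s6 - 0.5 * s6);
            Fx += fmag * dx / d; Fy += fmag * dy / d;
          });
          for (size_t k = 0; k < W.size(); ++k) {
            double rs = W.nx[k] * x + W.ny[k] * y - W.c[k] + 0.5 * sigma;
            if (rs >= cutoff) continue;
            if (rs < 0.05 * sigma) rs = 0.05 * sigma;
            double s2 = (sigma / rs) * (sigma / rs);
            double s6 = s2 * s2 * s2;
            double fmag = 48.0 * eps_J / (rs * 1e-6) * (s6 * s6 - 0.5 * s6);
            Fx += fmag * W.nx[k]; Fy += fmag * W.ny[k];
          }
        }

        double ex = std::cos(phi), ey = std::sin(phi);
        double vx = v0 * ex + vF_scale * Fx;   // um/s
        double vy = v0 * ey + vF_scale * Fy;
        double om = -rateB * std::sin(phi) + tauS_scale * (ex * Fy - ey * Fx);

        // adaptive elementary step: displacement- and stiffness-capped
        double dts = remaining;
        if (h < stiff_h && dts > dt / 10.0) dts = dt / 10.0;
        double speed = std::sqrt(vx * vx + vy * vy);
        if (speed * dts > max_disp) dts = max_disp / speed;
        double aom = std::fabs(om);
        if (aom * dts > 0.05) dts = 0.05 / aom;

        // propose, with rejection-resampling backstop against penetration
        bool accepted = false;
        double dts_try = dts;
        for (int attempt = 0; attempt <= 4; ++attempt) {
          double ampT = std::sqrt(2.0 * DT * dts_try);
          double ampR = std::sqrt(2.0 * DR * dts_try);
          double xn = x + vx * dts_try + ampT * R.norm();
          double yn = y + vy * dts_try + ampT * R.norm();
          double pn = phi + om * dts_try + ampR * R.norm();
          bool bad = grid.inside_any(xn, yn);
          if (!bad)
            for (size_t k = 0; k < W.size(); ++k)
              if (W.nx[k] * xn + W.ny[k] * yn - W.c[k] < 0) { bad = true; break; }
          if (!bad) {
            if (pn > M_PI) pn -= two_pi * std::floor((pn + M_PI) / two_pi);
            else if (pn <= -M_PI) pn -= two_pi * std::floor((pn + M_PI) / two_pi);
            px[i] = xn; py[i] = yn; pphi[i] = pn;
            remaining -= dts_try;
            accepted = true;
            break;
          }
          if (attempt == 0) dts_try = dts / 10.0;  // retry finer, fresh noise
        }
        if (!accepted) { ++n_reject; remaining -= dts; }

        // stop conditions, evaluated on the updated state
        if (stop_mode == 1 && px[i] >= x_stop) {
          active[i] = 0; --n_active;
          stop_time[i] = t + (dt - remaining);
          break;
        } else if (stop_mode == 2 || stop_mode == 3) {
          // committed escape (mode 2): crossed the plane x = x_stop;
          // barrier passage (mode 3): farther than the radius x_stop from
          // the apex (stop_cx, stop_cy). Both also require clearance from
          // every obstacle's interaction band.
          bool hit;
          if (stop_mode == 2) {
            hit = px[i] >= x_stop;
          } else {
            double ddx = px[i] - stop_cx, ddy = py[i] - stop_cy;
            hit = ddx * ddx + ddy * ddy >= x_stop * x_stop;
          }
          if (hit) {
            double h2, nnx, nny;
            grid.nearest(px[i], py[i], h2, nnx, nny);
            if (h2 > band) {
              active[i] = 0; --n_active;
              stop_time[i] = t + (dt - remaining);
              break;
            }
          }
        }
      }
    }

    if (record_frames && ((step + 1) % sample_every == 0)) {
      int f = (int)((step + 1) / sample_every);
      if (f < nframes) {
        for (int i = 0; i < n; ++i) {
          FX(i, f) = px[i]; FY(i, f) = py[i]; FPHI(i, f) = pphi[i];
        }
        frame_t[f] = (step + 1) * dt;
      }
    }
    if (stop_mode != 0 && n_active == 0) {
      if (record_frames) {  // fill remaining frames with frozen state
        for (long long s2 = step + 1; s2 < nsteps; ++s2) {
          if ((s2 + 1) % sample_every == 0) {
            int f = (int)((s2 + 1) / sample_every);
            if (f < nframes) {
              for (int i = 0; i < n; ++i) {
                FX(i, f) = px[i]; FY(i, f) = py[i]; FPHI(i, f) = pphi[i];
              }
              frame_t[f] = (s2 + 1) * dt;
            }
          }
        }
      }
      break;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector xf(n), yf(n), phif(n);
  for (int i = 0; i < n; ++i) { xf[i] = px[i]; yf[i] = py[i]; phif[i] = pphi[i]; }
  return List::create(_["x"] = xf, _["y"] = yf, _["phi"] = phif,
                      _["stop_time"] = stop_time,
                      _["frame_t"] = frame_t,
                      _["FX"] = FX, _["FY"] = FY, _["FPHI"] = FPHI,
                      _["n_reject"] = (double)n_reject,
                      _["min_h"] = min_h_seen);
}

// ---------------------------------------------------------------------------
// Local thickness of the fluid phase: for every fluid pixel, the diameter of
// the largest inscribed disc (fully in fluid) that contains it. Input is the
// Euclidean distance map D (pixels, distance to nearest solid pixel, 0 on
// solid), already capped by the caller. Painting proceeds from the largest
// discs down.

// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericMatrix local_thickness_cpp(NumericMatrix D) {
  const int nr = D.nrow(), nc = D.ncol();
  NumericMatrix LT(nr, nc);
  std::vector<int> idx;
  idx.reserve((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (D(i, j) > 0) idx.push_back(j * nr + i);
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return D[a] > D[b];
  });
  for (size_t k = 0; k < idx.size(); ++k) {
    int id = idx[k];
    int i = id % nr, j = id / nr;
    double r = D[id];
    double lt = 2.0 * r;
    int ri = (int)std::floor(r);
    for (int dj = -ri; dj <= ri; ++dj) {
      int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      double rem = r * r - (double)dj * dj;
      int di_max = (int)std::floor(std::sqrt(std::max(0.0, rem)));
      int ilo = std::max(0, i - di_max), ihi = std::min(nr - 1, i + di_max);
      for (int ii = ilo; ii <= ihi; ++ii)
        if (LT(ii, jj) < lt && D(ii, jj) > 0) LT(ii, jj) = lt;
    }
  }
  return LT;
}
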