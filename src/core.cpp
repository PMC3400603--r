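// Compiled core: sector sums on dense pheromone grids, deposit replay,
// synthetic trajectory generation, the off-lattice agent-based model and
// the Monte-Carlo random-walk oracle. All randomness goes through R's RNG
// (RNGScope in the generated wrappers), so set.seed() governs everything.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double R2D = 57.29577951308232;
static const double D2R = 0.017453292519943295;

// wrap angle to (-180, 180] (avoids fmod, whose symbol version differs
// across the glibc range this package is built on)
static inline double wrap180(double a) {
  a -= 360.0 * std::floor(a / 360.0 + 0.5);
  if (a <= -180.0) a += 360.0;
  return a;
}

// ---------------------------------------------------------------------------
// Sector sum on a grid. Grid rows index y, columns index x; cell (i, j) has
// its centre at (ox + (j + 0.5) * cell, oy + (i + 0.5) * cell). Membership is
// by cell centre: distance <= radius and relative bearing in [lo, hi]
// (degrees relative to `heading`, anticlockwise positive), with inclusive
// flags for each edge. Cells off-grid contribute 0; the cell centre
// coincident with the query point (undefined bearing) is skipped.
// ---------------------------------------------------------------------------
static double sector_scan(const double* g, int nr, int nc, double cell,
                          double ox, double oy, double x, double y,
                          double heading, double lo, double hi,
                          bool incl_lo, bool incl_hi, double radius) {
  int j0 = (int)std::floor((x - radius - ox) / cell) - 1;
  int j1 = (int)std::floor((x + radius - ox) / cell) + 1;
  int i0 = (int)std::floor((y - radius - oy) / cell) - 1;
  int i1 = (int)std::floor((y + radius - oy) / cell) + 1;
  if (j0 < 0) j0 = 0;
  if (i0 < 0) i0 = 0;
  if (j1 > nc - 1) j1 = nc - 1;
  if (i1 > nr - 1) i1 = nr - 1;
  double s = 0.0, r2 = radius * radius;
  for (int j = j0; j <= j1; ++j) {
    double cx = ox + (j + 0.5) * cell;
    double dx = cx - x;
    for (int i = i0; i <= i1; ++i) {
      double cy = oy + (i + 0.5) * cell;
      double dy = cy - y;
      double d2 = dx * dx + dy * dy;
      if (d2 > r2 || d2 < 1e-18) continue;
      double a = wrap180(std::atan2(dy, dx) * R2D - heading);
      bool in = (incl_lo ? a >= lo : a > lo) && (incl_hi ? a <= hi : a < hi);
      if (in) s += g[i + (size_t)j * nr];
    }
  }
  return s;
}

// [[Rcpp::export]]
double sector_sum_cpp(NumericMatrix grid, double cell, double ox, double oy,
                      double x, double y, double heading, double lo, double hi,
                      bool incl_lo, bool incl_hi, double radius) {
  return sector_scan(REAL(grid), grid.nrow(), grid.ncol(), cell, ox, oy, x, y,
                     heading, lo, hi, incl_lo, incl_hi, radius);
}

// ---------------------------------------------------------------------------
// Footprint rasterization: for each trajectory sample, the cells whose
// centres lie within `fp_radius` of the sample point. Returns flat 0-based
// cell indices plus the per-sample cell count (used to split the per-sample
// deposit so each ant lays 1 unit * mm^-2-equivalent per second in total).
// ---------------------------------------------------------------------------
static void footprint_cells(double x, double y, int nr, int nc, double cell,
                            double ox, double oy, double fp_radius,
                            std::vector<int>& out) {
  out.clear();
  int j0 = (int)std::floor((x - fp_radius - ox) / cell) - 1;
  int j1 = (int)std::floor((x + fp_radius - ox) / cell) + 1;
  int i0 = (int)std::floor((y - fp_radius - oy) / cell) - 1;
  int i1 = (int)std::floor((y + fp_radius - oy) / cell) + 1;
  if (j0 < 0) j0 = 0;
  if (i0 < 0) i0 = 0;
  if (j1 > nc - 1) j1 = nc - 1;
  if (i1 > nr - 1) i1 = nr - 1;
  double r2 = fp_radius * fp_radius;
  for (int j = j0; j <= j1; ++j) {
    double dx = ox + (j + 0.5) * cell - x;
    for (int i = i0; i <= i1; ++i) {
      double dy = oy + (i + 0.5) * cell - y;
      if (dx * dx + dy * dy <= r2) out.push_back(i + j * nr);
    }
  }
}

// [[Rcpp::export]]
List traj_footprints_cpp(NumericVector x, NumericVector y, int nr, int nc,
                         double cell, double ox, double oy, double fp_radius) {
  int n = x.size();
  std::vector<int> cells, sample;
  std::vector<int> buf;
  cells.reserve(5 * (size_t)n);
  sample.reserve(5 * (size_t)n);
  IntegerVector ncells(n);
  for (int s = 0; s < n; ++s) {
    footprint_cells(x[s], y[s], nr, nc, cell, ox, oy, fp_radius, buf);
    ncells[s] = (int)buf.size();
    for (size_t k = 0; k < buf.size(); ++k) {
      cells.push_back(buf[k]);
      sample.push_back(s + 1);  // 1-based sample index for R
    }
  }
  return List::create(_["cell"] = wrap(cells), _["sample"] = wrap(sample),
                      _["n_cells"] = ncells);
}

// ---------------------------------------------------------------------------
// Replay a time-ordered deposit stream and annotate events with lagged
// left/right sector sums. Evaporation (half-life hl, possibly Inf) is exact:
// a deposit dq at time t is stored as dq * 2^(t/hl) and every query at time
// T is scaled by 2^(-T/hl). Events must be sorted by query time ev_T.
// Left sector spans [0, 2*half_angle] relative to the heading (boundary ray
// to the left), right spans [-2*half_angle, 0).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix replay_annotate_cpp(NumericVector dep_t, IntegerVector dep_cell,
                                  NumericVector dep_dq, int nr, int nc,
                                  double cell, double ox, double oy,
                                  double half_life, NumericVector ev_x,
                                  NumericVector ev_y, NumericVector ev_heading,
                                  NumericVector ev_T, double radius,
                                  double half_angle) {
  int nev = ev_x.size(), ndep = dep_t.size();
  std::vector<double> field((size_t)nr * nc, 0.0);
  bool evap = R_finite(half_life);
  NumericMatrix out(nev, 2);
  int p = 0;
  for (int e = 0; e < nev; ++e) {
    double T = ev_T[e];
    while (p < ndep && dep_t[p] <= T + 1e-9) {
      double amp = evap ? std::pow(2.0, dep_t[p] / half_life) : 1.0;
      field[dep_cell[p]] += dep_dq[p] * amp;
      ++p;
    }
    double fac = evap ? std::pow(2.0, -T / half_life) : 1.0;
    double L = sector_scan(field.data(), nr, nc, cell, ox, oy, ev_x[e], ev_y[e],
                           ev_heading[e], 0.0, 2.0 * half_angle, true, true,
                           radius);
    double R = sector_scan(field.data(), nr, nc, cell, ox, oy, ev_x[e], ev_y[e],
                           ev_heading[e], -2.0 * half_angle, 0.0, true, false,
                           radius);
    out(e, 0) = L * fac;
    out(e, 1) = R * fac;
  }
  return out;
}

// Same replay machinery, but instead of sector sums it samples the field at
// mirror pixel pairs: for each event and each (forward, lateral) offset in
// the ant frame (forward along the heading, lateral > 0 to the left), the
// value of the cell containing pos + forward*u + lateral*u_left and its
// mirror (lateral -> -lateral). Off-grid points give NA.
// [[Rcpp::export]]
List replay_offsets_cpp(NumericVector dep_t, IntegerVector dep_cell,
                        NumericVector dep_dq, int nr, int nc, double cell,
                        double ox, double oy, double half_life,
                        NumericVector ev_x, NumericVector ev_y,
                        NumericVector ev_heading, NumericVector ev_T,
                        NumericVector off_forward, NumericVector off_lateral) {
  int nev = ev_x.size(), ndep = dep_t.size(), noff = off_forward.size();
  std::vector<double> field((size_t)nr * nc, 0.0);
  bool evap = R_finite(half_life);
  NumericMatrix PL(nev, noff), PR(nev, noff);
  int p = 0;
  for (int e = 0; e < nev; ++e) {
    double T = ev_T[e];
    while (p < ndep && dep_t[p] <= T + 1e-9) {
      double amp = evap ? std::pow(2.0, dep_t[p] / half_life) : 1.0;
      field[dep_cell[p]] += dep_dq[p] * amp;
      ++p;
    }
    double fac = evap ? std::pow(2.0, -T / half_life) : 1.0;
    double th = ev_heading[e] * D2R;
    double ux = std::cos(th), uy = std::sin(th);
    // unit vector to the left of the heading (anticlockwise +90 deg)
    double lx = -uy, ly = ux;
    for (int o = 0; o < noff; ++o) {
      for (int side = 0; side < 2; ++side) {
        double lat = side == 0 ? off_lateral[o] : -off_lateral[o];
        double px = ev_x[e] + off_forward[o] * ux + lat * lx;
        double py = ev_y[e] + off_forward[o] * uy + lat * ly;
        int j = (int)std::floor((px - ox) / cell);
        int i = (int)std::floor((py - oy) / cell);
        double v = NA_REAL;
        if (i >= 0 && i < nr && j >= 0 && j < nc)
          v = field[i + (size_t)j * nr] * fac;
        if (side == 0) PL(e, o) = v; else PR(e, o) = v;
      }
    }
  }
  return List::create(_["left"] = PL, _["right"] = PR);
}

// ---------------------------------------------------------------------------
// Synthetic Weber walker generator. Agents move at constant speed in a
// rectangular arena [0,W]x[0,H], updating heading every `turn_frames`
// frames. The turning angle responds to the pheromone field as it was
// `lag_s` seconds earlier (the same lagged quantity the inference
// annotates): dalpha = A*(CL-CR)/(CL+CR) + N(0, noise_sd) when CL+CR >= C0,
// else N(0, wide_sd). Deposits co-evolve the field (occupancy-deduplicated
// per frame) unless a static field is supplied. Segments that would leave
// the arena are redirected towards the centre (flagged `wall` in the log).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List gen_weber_traj_cpp(int n_ants, double duration, double fps,
                        double speed_mms, double A, double noise_sd,
                        double wide_sd, double C0, double lag_s,
                        int turn_frames, double W, double H, double cell,
                        double fp_radius, double half_life,
                        double sense_radius, double sense_half_angle,
                        Nullable<NumericMatrix> static_field) {
  int n_frames = (int)std::lround(duration * fps);
  double dtf = 1.0 / fps;
  double step = speed_mms * dtf;
  int nr = (int)std::lround(H / cell), nc = (int)std::lround(W / cell);
  double ox = 0.0, oy = 0.0;
  bool is_static = static_field.isNotNull();
  NumericMatrix sfield;
  if (is_static) {
    sfield = NumericMatrix(static_field);
    nr = sfield.nrow(); nc = sfield.ncol();
  }
  std::vector<double> field((size_t)nr * nc, 0.0);
  bool evap = R_finite(half_life);
  int lag_frames = (int)std::lround(lag_s * fps);

  std::vector<double> x(n_ants), y(n_ants), hd(n_ants);
  double margin = 2.0 * cell;
  for (int a = 0; a < n_ants; ++a) {
    x[a] = margin + unif_rand() * (W - 2 * margin);
    y[a] = margin + unif_rand() * (H - 2 * margin);
    hd[a] = unif_rand() * 360.0 - 180.0;
  }

  // trajectory store
  std::vector<double> tx((size_t)n_ants * n_frames), ty((size_t)n_ants * n_frames);
  // truth log
  std::vector<int> lg_ant; std::vector<double> lg_t, lg_da, lg_cl, lg_cr;
  std::vector<int> lg_above, lg_wall;

  // ring buffer of per-frame deduplicated deposits
  std::vector<std::vector<std::pair<int, double> > > ring(
      std::max(lag_frames, 1));
  std::vector<int> stamp((size_t)nr * nc, -1);
  std::vector<int> buf;

  double seg_len = step * turn_frames;
  for (int f = 0; f < n_frames; ++f) {
    double t = f * dtf;
    // bring the lagged field up to date: deposits from frame f - lag_frames
    if (!is_static && lag_frames > 0 && f >= lag_frames) {
      std::vector<std::pair<int, double> >& fr = ring[(f - lag_frames) % lag_frames];
      double td = (f - lag_frames) * dtf;
      double amp = evap ? std::pow(2.0, td / half_life) : 1.0;
      for (size_t k = 0; k < fr.size(); ++k)
        field[fr[k].first] += fr[k].second * amp;
      fr.clear();
    }
    double Tq = t - lag_s;
    double fac = (evap && Tq > 0) ? std::pow(2.0, -Tq / half_life) : 1.0;
    for (int a = 0; a < n_ants; ++a) {
      // record position at this frame
      tx[(size_t)a * n_frames + f] = x[a];
      ty[(size_t)a * n_frames + f] = y[a];
      // turning update
      if (f > 0 && f % turn_frames == 0) {
        double L = 0.0, R = 0.0;
        const double* g = is_static ? REAL(sfield) : field.data();
        double qfac = is_static ? 1.0 : ((!is_static && Tq < 0) ? 0.0 : fac);
        if (is_static || Tq >= 0) {
          L = qfac * sector_scan(g, nr, nc, cell, ox, oy, x[a], y[a], hd[a],
                                 0.0, 2.0 * sense_half_angle, true, true,
                                 sense_radius);
          R = qfac * sector_scan(g, nr, nc, cell, ox, oy, x[a], y[a], hd[a],
                                 -2.0 * sense_half_angle, 0.0, true, false,
                                 sense_radius);
        }
        bool above = (L + R) >= C0;
        double da;
        if (above) da = A * (L - R) / (L + R) + norm_rand() * noise_sd;
        else da = norm_rand() * wide_sd;
        double newh = hd[a] + da;
        // wall avoidance: redirect towards the centre if the next straight
        // segment would leave the arena
        bool wall = false;
        for (int tries = 0; tries < 20; ++tries) {
          double ex = x[a] + seg_len * std::cos(newh * D2R);
          double ey = y[a] + seg_len * std::sin(newh * D2R);
          if (ex > margin && ex < W - margin && ey > margin && ey < H - margin)
            break;
          wall = true;
          double toc = std::atan2(H / 2.0 - y[a], W / 2.0 - x[a]) * R2D;
          newh = (tries < 19) ? toc + norm_rand() * wide_sd : toc;
        }
        double da_exec = wrap180(newh - hd[a]);
        hd[a] = wrap180(newh);
        lg_ant.push_back(a + 1); lg_t.push_back(t); lg_da.push_back(da_exec);
        lg_cl.push_back(L); lg_cr.push_back(R);
        lg_above.push_back(above ? 1 : 0); lg_wall.push_back(wall ? 1 : 0);
      }
      // deposit at the current position (occupancy: once per cell per frame)
      if (!is_static && lag_frames > 0) {
        footprint_cells(x[a], y[a], nr, nc, cell, ox, oy, fp_radius, buf);
        if (!buf.empty()) {
          double dq = dtf / (double)buf.size();
          std::vector<std::pair<int, double> >& fr = ring[f % lag_frames];
          for (size_t k = 0; k < buf.size(); ++k) {
            if (stamp[buf[k]] != f) {
              stamp[buf[k]] = f;
              fr.push_back(std::make_pair(buf[k], dq));
            }
          }
        }
      }
      // move
      x[a] += step * std::cos(hd[a] * D2R);
      y[a] += step * std::sin(hd[a] * D2R);
    }
  }

  IntegerVector ant_id((size_t)n_ants * n_frames);
  NumericVector tt((size_t)n_ants * n_frames);
  for (int a = 0; a < n_ants; ++a)
    for (int f = 0; f < n_frames; ++f) {
      ant_id[(size_t)a * n_frames + f] = a + 1;
      tt[(size_t)a * n_frames + f] = f * dtf;
    }
  return List::create(
      _["ant_id"] = ant_id, _["t_s"] = tt, _["x_mm"] = wrap(tx),
      _["y_mm"] = wrap(ty),
      _["log"] = List::create(_["ant_id"] = wrap(lg_ant), _["t_s"] = wrap(lg_t),
                              _["dalpha_true"] = wrap(lg_da),
                              _["CL_true"] = wrap(lg_cl),
                              _["CR_true"] = wrap(lg_cr),
                              _["above_threshold"] = wrap(lg_above),
                              _["wall"] = wrap(lg_wall)));
}

// ---------------------------------------------------------------------------
// Monte-Carlo biased random walk oracle: x_{t+1} = x_t + V + N(0, sigma),
// x_0 = 0, n steps; positive displacement = towards the left branch.
// Returns the fraction of walkers finishing at x > 0.
// ---------------------------------------------------------------------------
// Antithetic pairs: each drawn noise path is used with both signs, which
// leaves the estimator unbiased while cutting its variance below the
// binomial level (so a binomial-SE error bound on it is conservative).
// [[Rcpp::export]]
double mc_walk_cpp(int n_walkers, int n_steps, double V, double sigma) {
  long n_pairs = n_walkers / 2;
  long left = 0;
  for (long w = 0; w < n_pairs; ++w) {
    double s_noise = 0.0;
    for (int s = 0; s < n_steps; ++s) s_noise += norm_rand();
    if (n_steps * V + sigma * s_noise > 0) ++left;
    if (n_steps * V - sigma * s_noise > 0) ++left;
  }
  return (double)left / (double)(2 * n_pairs);
}

// Nonparametric bootstrap of the through-origin OLS slope sum(xy)/sum(xx).
// [[Rcpp::export]]
NumericVector boot_origin_slope_cpp(NumericVector x, NumericVector y,
                                    int n_boot) {
  int n = x.size();
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    double sxy = 0.0, sxx = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      sxy += x[j] * y[j];
      sxx += x[j] * x[j];
    }
    out[b] = sxx > 0 ? sxy / sxx : NA_REAL;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Agent-based model. Geometry 0 = open circular arena (radius arena_r,
// centred at the origin, nest at the centre); geometry 1 = binary bridge
// (nest disc, proximal stem, symmetric diamond of four 45-degree branch
// capsules, distal stem, food disc; versioned constants passed from R).
// One call advances the world n_steps steps of dt seconds; agents update in
// fixed id order.
// ---------------------------------------------------------------------------
struct BridgeGeom {
  double w;       // corridor half-width
  double y_nest, y1, y2, y_food, vx, region_r;
};

static inline double dist2seg(double px, double py, double ax, double ay,
                              double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double t = ((px - ax) * vx + (py - ay) * vy) / (vx * vx + vy * vy);
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
  return std::sqrt(dx * dx + dy * dy);
}

// Fast combined left/right sector sum used by the ABM inner loop: one pass
// over the disc (column-wise y-limited), membership by cross products with
// the sector boundary unit vectors (each sector spans < 180 degrees).
// Equivalent to two sector_scan calls up to floating-point ties on the
// boundary rays.
static void sector_pair_scan(const double* g, int nr, int nc, double cell,
                             double ox, double oy, double x, double y,
                             double heading, double off, double hw,
                             double radius, double& L, double& R) {
  double aLlo = (heading + off - hw) * D2R, aLhi = (heading + off + hw) * D2R;
  double aRlo = (heading - off - hw) * D2R, aRhi = (heading - off + hw) * D2R;
  double Llox = std::cos(aLlo), Lloy = std::sin(aLlo);
  double Lhix = std::cos(aLhi), Lhiy = std::sin(aLhi);
  double Rlox = std::cos(aRlo), Rloy = std::sin(aRlo);
  double Rhix = std::cos(aRhi), Rhiy = std::sin(aRhi);
  L = 0.0; R = 0.0;
  double r2 = radius * radius;
  int j0 = (int)std::floor((x - radius - ox) / cell);
  int j1 = (int)std::floor((x + radius - ox) / cell);
  if (j0 < 0) j0 = 0;
  if (j1 > nc - 1) j1 = nc - 1;
  for (int j = j0; j <= j1; ++j) {
    double dx = ox + (j + 0.5) * cell - x;
    double rem = r2 - dx * dx;
    if (rem < 0) continue;
    double dylim = std::sqrt(rem);
    int i0 = (int)std::ceil((y - dylim - oy) / cell - 0.5);
    int i1 = (int)std::floor((y + dylim - oy) / cell - 0.5);
    if (i0 < 0) i0 = 0;
    if (i1 > nr - 1) i1 = nr - 1;
    const double* col = g + (size_t)j * nr;
    for (int i = i0; i <= i1; ++i) {
      double v = col[i];
      if (v == 0.0) continue;
      double dy = oy + (i + 0.5) * cell - y;
      if (dx == 0.0 && dy == 0.0) continue;
      if (Llox * dy - Lloy * dx >= 0 && dx * Lhiy - dy * Lhix >= 0) L += v;
      else if (Rlox * dy - Rloy * dx >= 0 && dx * Rhiy - dy * Rhix >= 0)
        R += v;
    }
  }
}

// parts: 0 stem1, 1 Llow, 2 Lup, 3 Rlow, 4 Rup, 5 stem2, 6 nest, 7 food
static void bridge_parts(const BridgeGeom& G, double px, double py,
                         bool in[8]) {
  double ym = (G.y1 + G.y2) / 2.0;
  in[0] = std::fabs(px) <= G.w && py >= G.y_nest && py <= G.y1;
  in[1] = dist2seg(px, py, 0, G.y1, -G.vx, ym) <= G.w;
  in[2] = dist2seg(px, py, -G.vx, ym, 0, G.y2) <= G.w;
  in[3] = dist2seg(px, py, 0, G.y1, G.vx, ym) <= G.w;
  in[4] = dist2seg(px, py, G.vx, ym, 0, G.y2) <= G.w;
  in[5] = std::fabs(px) <= G.w && py >= G.y2 && py <= G.y_food;
  double dn = std::sqrt(px * px + (py - G.y_nest) * (py - G.y_nest));
  double df = std::sqrt(px * px + (py - G.y_food) * (py - G.y_food));
  in[6] = dn <= G.region_r;
  in[7] = df <= G.region_r;
}

static bool bridge_inside(const BridgeGeom& G, double px, double py) {
  bool in[8];
  bridge_parts(G, px, py, in);
  for (int k = 0; k < 8; ++k) if (in[k]) return true;
  return false;
}

// axis unit vectors (pointing nest -> food) per part
static void bridge_axis(const BridgeGeom& G, int part, double& ax,
                        double& ay) {
  const double s = 0.7071067811865476;
  switch (part) {
    case 1: ax = -s; ay = s; break;
    case 2: ax = s; ay = s; break;
    case 3: ax = s; ay = s; break;
    case 4: ax = -s; ay = s; break;
    default: ax = 0.0; ay = 1.0;
  }
}

// Fix mirrored diamond: part 3 (R lower) runs (0,y1)->(vx,ym): axis (s, s).
// part 4 (R upper) runs (vx,ym)->(0,y2): axis (-s, s). (Set above.)

// [[Rcpp::export]]
List abm_run_cpp(List state, List config, int n_steps, bool record_seconds,
                 bool record_occupancy, int checkpoint_steps) {
  // ---- unpack state
  NumericVector px = clone(as<NumericVector>(state["x"]));
  NumericVector py = clone(as<NumericVector>(state["y"]));
  NumericVector hd = clone(as<NumericVector>(state["heading"]));
  IntegerVector inw = clone(as<IntegerVector>(state["in_world"]));
  IntegerVector lab = clone(as<IntegerVector>(state["label"]));
  IntegerVector last_food = clone(as<IntegerVector>(state["last_food"]));
  IntegerVector sst = clone(as<IntegerVector>(state["steps_since_turn"]));
  NumericMatrix field = clone(as<NumericMatrix>(state["field"]));
  double t = as<double>(state["t"]);
  double moves = as<double>(state["moves"]);
  int n_ants = px.size();
  int nr = field.nrow(), nc = field.ncol();

  // ---- unpack config
  int geometry = as<int>(config["geometry"]);
  double cell = as<double>(config["patch_size"]);
  double ox = as<double>(config["origin_x"]), oy = as<double>(config["origin_y"]);
  double dt = as<double>(config["dt"]);
  double speed = as<double>(config["speed"]);
  int turn_every = as<int>(config["turn_every"]);
  double A = as<double>(config["A"]);
  double s1 = as<double>(config["sigma1"]), s2 = as<double>(config["sigma2"]);
  double sense_r = as<double>(config["sense_radius"]);
  double sense_off = as<double>(config["sense_offset"]);
  double sense_hw = as<double>(config["sense_half_angle"]);
  double deposit = as<double>(config["deposit"]);
  double entry_p = as<double>(config["entry_prob"]);
  double btn_p = as<double>(config["return_prob"]);
  double thresh = as<double>(config["detection_threshold"]);
  double hl = as<double>(config["evap_half_life"]);
  double arena_r = as<double>(config["arena_radius"]);
  double homing_r = as<double>(config["homing_radius"]);
  BridgeGeom G;
  G.w = as<double>(config["bridge_half_width"]);
  G.y_nest = as<double>(config["bridge_y_nest"]);
  G.y1 = as<double>(config["bridge_y1"]);
  G.y2 = as<double>(config["bridge_y2"]);
  G.y_food = as<double>(config["bridge_y_food"]);
  G.vx = as<double>(config["bridge_vertex_x"]);
  G.region_r = as<double>(config["bridge_region_r"]);
  double nest_x = 0.0, nest_y = (geometry == 1) ? G.y_nest : 0.0;
  bool evap = R_finite(hl);

  // per-second records
  int steps_per_sec = (int)std::lround(1.0 / dt);
  std::vector<double> rec_t, rec_l, rec_r, rec_else, rec_inworld;
  // occupancy / checkpoints
  std::vector<IntegerMatrix> occ_blocks;
  IntegerMatrix occ;
  if (record_occupancy) occ = IntegerMatrix(nr, nc);
  std::vector<double> gini_t, gini_v;

  double* g = REAL(field);

  for (int s = 0; s < n_steps; ++s) {
    t += dt;
    double fac = evap ? std::pow(2.0, -t / hl) : 1.0;
    for (int a = 0; a < n_ants; ++a) {
      if (!inw[a]) {
        if (unif_rand() < entry_p) {
          inw[a] = 1; lab[a] = 0; last_food[a] = 0; sst[a] = 0;
          px[a] = nest_x; py[a] = nest_y;
          hd[a] = (geometry == 1) ? 90.0 : unif_rand() * 360.0 - 180.0;
        }
        continue;
      }
      sst[a] += 1;
      double dxn = px[a] - nest_x, dyn = py[a] - nest_y;
      double dnest = std::sqrt(dxn * dxn + dyn * dyn);
      bool homing = lab[a] && dnest <= homing_r;
      if (homing) {
        if (dnest <= speed) {  // reached the nest: leave the world
          inw[a] = 0; lab[a] = 0;
          continue;
        }
        hd[a] = std::atan2(nest_y - py[a], nest_x - px[a]) * R2D;
      } else if (sst[a] >= turn_every) {
        sst[a] = 0;
        double L, R;
        sector_pair_scan(g, nr, nc, cell, ox, oy, px[a], py[a], hd[a],
                         sense_off, sense_hw, sense_r, L, R);
        L *= fac; R *= fac;
        double da = (L + R >= thresh)
                        ? A * (L - R) / (L + R) + norm_rand() * s1
                        : norm_rand() * s2;
        hd[a] = wrap180(hd[a] + da);
      }
      // propose move, apply border rule
      double nx = px[a] + speed * std::cos(hd[a] * D2R);
      double ny = py[a] + speed * std::sin(hd[a] * D2R);
      bool ok;
      if (geometry == 0) ok = (nx * nx + ny * ny) <= arena_r * arena_r;
      else ok = bridge_inside(G, nx, ny);
      if (!ok) {
        if (geometry == 0) {
          // align with the wall tangent closest to the current heading;
          // exact head-on tie broken towards the left tangent
          double radial = std::atan2(py[a], px[a]) * R2D;
          double tl = wrap180(radial + 90.0), tr = wrap180(radial - 90.0);
          double dl = std::fabs(wrap180(tl - hd[a]));
          double dr = std::fabs(wrap180(tr - hd[a]));
          hd[a] = (dl <= dr) ? tl : tr;
        } else {
          // align with the corridor axis pointing away from the latest
          // visited site; among containing parts pick the axis closest to
          // the current heading
          bool in[8];
          bridge_parts(G, px[a], py[a], in);
          double sgn = last_food[a] ? -1.0 : 1.0;
          double best = -2.0, bh = hd[a];
          double hx = std::cos(hd[a] * D2R), hy = std::sin(hd[a] * D2R);
          for (int k = 0; k < 8; ++k) {
            if (!in[k]) continue;
            double ax, ay;
            bridge_axis(G, k, ax, ay);
            ax *= sgn; ay *= sgn;
            double dot = ax * hx + ay * hy;
            if (dot > best) { best = dot; bh = std::atan2(ay, ax) * R2D; }
          }
          hd[a] = bh;
        }
        nx = px[a] + speed * std::cos(hd[a] * D2R);
        ny = py[a] + speed * std::sin(hd[a] * D2R);
        if (geometry == 0) {
          double rn = std::sqrt(nx * nx + ny * ny);
          if (rn > arena_r) { nx = nx * (arena_r - 1e-6) / rn; ny = ny * (arena_r - 1e-6) / rn; }
          ok = true;
        } else {
          ok = bridge_inside(G, nx, ny);
        }
      }
      if (ok) {
        px[a] = nx; py[a] = ny;
        moves += 1;
        int j = (int)std::floor((px[a] - ox) / cell);
        int i = (int)std::floor((py[a] - oy) / cell);
        if (i >= 0 && i < nr && j >= 0 && j < nc) {
          double amp = evap ? std::pow(2.0, t / hl) : 1.0;
          g[i + (size_t)j * nr] += deposit * amp;
        }
      }
      // labels
      if (geometry == 1) {
        if (!lab[a]) {
          double dxf = px[a], dyf = py[a] - G.y_food;
          if (std::sqrt(dxf * dxf + dyf * dyf) <= G.region_r) {
            lab[a] = 1; last_food[a] = 1;
          }
        }
      } else {
        if (!lab[a] && unif_rand() < btn_p) lab[a] = 1;
      }
    }
    // per-second records
    bool second_tick = ((s + 1) % steps_per_sec) == 0;
    if (second_tick && (record_seconds || record_occupancy)) {
      int nl = 0, nrgt = 0, nelse = 0, niw = 0;
      for (int a = 0; a < n_ants; ++a) {
        if (!inw[a]) continue;
        ++niw;
        if (geometry == 1) {
          bool in[8];
          bridge_parts(G, px[a], py[a], in);
          bool branchL = (in[1] || in[2]) && std::fabs(px[a]) > G.w;
          bool branchR = (in[3] || in[4]) && std::fabs(px[a]) > G.w;
          if (branchL) ++nl;
          else if (branchR) ++nrgt;
          else ++nelse;
        }
        if (record_occupancy) {
          int j = (int)std::floor((px[a] - ox) / cell);
          int i = (int)std::floor((py[a] - oy) / cell);
          if (i >= 0 && i < nr && j >= 0 && j < nc) occ(i, j) += 1;
        }
      }
      if (record_seconds) {
        rec_t.push_back(t); rec_l.push_back(nl); rec_r.push_back(nrgt);
        rec_else.push_back(nelse); rec_inworld.push_back(niw);
      }
    }
    // checkpoints: spatial Gini of the field + occupancy block rollover
    if (checkpoint_steps > 0 && ((s + 1) % checkpoint_steps) == 0) {
      std::vector<double> vals;
      vals.reserve((size_t)nr * nc);
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (geometry == 0) {
            double cx = ox + (j + 0.5) * cell, cy = oy + (i + 0.5) * cell;
            if (cx * cx + cy * cy > arena_r * arena_r) continue;
          }
          vals.push_back(g[i + (size_t)j * nr]);
        }
      std::sort(vals.begin(), vals.end());
      long double tot = 0.0, acc = 0.0;
      size_t n = vals.size();
      for (size_t k = 0; k < n; ++k) {
        tot += vals[k];
        acc += (long double)(k + 1) * vals[k];
      }
      double gini = (tot > 0) ? (double)(2.0L * acc / ((long double)n * tot) -
                                         ((long double)n + 1) / (long double)n)
                              : 0.0;
      gini_t.push_back(t);
      gini_v.push_back(gini);
      if (record_occupancy) {
        occ_blocks.push_back(clone(occ));
        occ = IntegerMatrix(nr, nc);
      }
    }
  }

  // rescale stored amplitudes back to time-t units
  if (evap) {
    double fac = std::pow(2.0, -t / hl);
    for (size_t k = 0; k < (size_t)nr * nc; ++k) g[k] *= fac;
  }
  List out_state = List::create(
      _["x"] = px, _["y"] = py, _["heading"] = hd, _["in_world"] = inw,
      _["label"] = lab, _["last_food"] = last_food,
      _["steps_since_turn"] = sst, _["field"] = field, _["t"] = t,
      _["moves"] = moves);
  List counts = List::create(_["t_s"] = wrap(rec_t), _["n_left"] = wrap(rec_l),
                             _["n_right"] = wrap(rec_r),
                             _["n_elsewhere"] = wrap(rec_else),
                             _["n_in_world"] = wrap(rec_inworld));
  List occl(occ_blocks.size());
  for (size_t k = 0; k < occ_blocks.size(); ++k) occl[k] = occ_blocks[k];
  return List::create(_["state"] = out_state, _["counts"] = counts,
                      _["gini_t"] = wrap(gini_t), _["gini"] = wrap(gini_v),
                      _["occupancy"] = occl);
}

// [[Rcpp::export]]
bool bridge_inside_cpp(List config, double x, double y) {
  BridgeGeom G;
  G.w = as<double>(config["bridge_half_width"]);
  G.y_nest = as<double>(config["bridge_y_nest"]);
  G.y1 = as<double>(config["bridge_y1"]);
  G.y2 = as<double>(config["bridge_y2"]);
  G.y_food = as<double>(config["bridge_y_food"]);
  G.vx = as<double>(config["bridge_vertex_x"]);
  G.region_r = as<double>(config["bridge_region_r"]);
  return bridge_inside(G, x, y);
}
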