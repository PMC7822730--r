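// Event-driven molecular dynamics of polydisperse spheres with a pairwise
// square-well attraction, plus configuration utilities (overlap relaxation,
// pair histograms, effective structure factors).
//
// Conventions: equal unit masses, kT = 1, periodic cubic box of side L.
// Core contact of pair (i,j) at sigma_ij = R_i + R_j; well outer edge at
// (1 + delta) * sigma_ij with depth u (in kT). Exact piecewise-ballistic
// dynamics; events are kept in a binary heap with lazy invalidation via
// per-particle event counters.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Event {
  double t;
  int i, j;        // pair partner, or axis*2+dir code for cell crossings
  int kind;        // 0 pair event, 1 cell crossing
  unsigned ci, cj; // counters at scheduling time
  bool operator<(const Event& o) const { return t > o.t; } // min-heap
};

struct Sim {
  int N;
  double L, u, delta;
  bool well;
  std::vector<double> R;
  std::vector<double> x, v;      // 3N, positions unwrapped within box frame
  std::vector<double> tlast;     // per-particle last update time
  std::vector<unsigned> cnt;
  double now = 0.0;
  // cells
  int nc;
  double cellL;
  std::vector<int> head, nxt, cellof;
  // bonds (pairs inside well)
  std::unordered_set<long long> bonds;
  std::priority_queue<Event> pq;
  // accumulators
  double virial = 0.0;           // sum of mu*dvn*r over events
  long long n_pair_events = 0;

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * N + j;
  }
  bool bonded(int i, int j) const { return bonds.count(key(i, j)) > 0; }

  double wrap(double a) const {
    a -= L * std::floor(a / L);
    if (a >= L) a -= L;   // guard against floor rounding at the edge
    if (a < 0) a = 0;
    return a;
  }

  void cell_insert(int i) {
    int cx = (int)(x[3 * i] / cellL), cy = (int)(x[3 * i + 1] / cellL),
        cz = (int)(x[3 * i + 2] / cellL);
    if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1; if (cz >= nc) cz = nc - 1;
    if (cx < 0) cx = 0; if (cy < 0) cy = 0; if (cz < 0) cz = 0;
    cell_insert_at(i, (cx * nc + cy) * nc + cz);
  }
  void cell_insert_at(int i, int c) {
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  void cell_remove(int i) {
    int c = cellof[i];
    int p = head[c];
    if (p == i) { head[c] = nxt[i]; return; }
    while (p >= 0 && nxt[p] != i) p = nxt[p];
    if (p >= 0) nxt[p] = nxt[i];
  }

  void advance(int i, double t) {
    double dt = t - tlast[i];
    x[3 * i] += v[3 * i] * dt;
    x[3 * i + 1] += v[3 * i + 1] * dt;
    x[3 * i + 2] += v[3 * i + 2] * dt;
    tlast[i] = t;
  }

  // minimum-image relative position j -> i at their (already advanced) times
  void relpos(int i, int j, double* r) const {
    for (int k = 0; k < 3; ++k) {
      double d = x[3 * i + k] - x[3 * j + k];
      d -= L * std::round(d / L);
      r[k] = d;
    }
  }

  // predict and push the next event for pair (i, j); both must be advanced
  // to time `now`
  void predict_pair(int i, int j) {
    double r[3], w[3];
    relpos(i, j, r);
    for (int k = 0; k < 3; ++k) w[k] = v[3 * i + k] - v[3 * j + k];
    double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
    double b = r[0] * w[0] + r[1] * w[1] + r[2] * w[2];
    double v2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    if (v2 <= 0) return;
    double sig = R[i] + R[j];
    double t_evt = -1.0;
    if (!well) {
      if (b < 0) {
        double disc = b * b - v2 * (r2 - sig * sig);
        if (disc > 0) t_evt = (-b - std::sqrt(disc)) / v2;
      }
    } else {
      double rw = (1.0 + delta) * sig;
      if (bonded(i, j)) {
        // inside the well: core collision if approaching and reachable,
        // otherwise well-exit attempt
        double disc_c = b * b - v2 * (r2 - sig * sig);
        if (b < 0 && disc_c > 0) {
          t_evt = (-b - std::sqrt(disc_c)) / v2;
        } else {
          double disc_w = b * b - v2 * (r2 - rw * rw); // >= b^2 inside
          t_evt = (-b + std::sqrt(std::max(disc_w, 0.0))) / v2;
        }
      } else {
        if (b < 0) {
          double disc = b * b - v2 * (r2 - rw * rw);
          if (disc > 0) t_evt = (-b - std::sqrt(disc)) / v2;
        }
      }
    }
    if (t_evt < -1e-12) return;
    if (t_evt < 0) t_evt = 0;
    pq.push({now + t_evt, i, j, 0, cnt[i], cnt[j]});
  }

  // time for particle i (advanced to now) to cross its cell boundary;
  // the crossing axis and direction are encoded in the event so that the
  // cell index moves deterministically (recomputing it from the position
  // can loop when the particle sits exactly on a boundary)
  void predict_cell(int i) {
    int c = cellof[i];
    int cz = c % nc, cy = (c / nc) % nc, cx = c / (nc * nc);
    int cc[3] = {cx, cy, cz};
    double tmin = std::numeric_limits<double>::infinity();
    int code = -1;
    for (int k = 0; k < 3; ++k) {
      double vk = v[3 * i + k];
      if (vk > 1e-14) {
        double bnd = (cc[k] + 1) * cellL;
        double t = (bnd - x[3 * i + k]) / vk;
        if (t < tmin) { tmin = t; code = k * 2 + 1; }
      } else if (vk < -1e-14) {
        double bnd = cc[k] * cellL;
        double t = (bnd - x[3 * i + k]) / vk;
        if (t < tmin) { tmin = t; code = k * 2; }
      }
    }
    if (std::isfinite(tmin) && code >= 0) {
      if (tmin < 0) tmin = 0;
      pq.push({now + tmin, i, code, 1, cnt[i], 0});
    }
  }

  // process a cell crossing: snap the coordinate to the boundary, step the
  // cell index along the stored axis, wrapping through the periodic box
  void do_cell_cross(int i, int code) {
    int axis = code / 2, dir = (code % 2) ? +1 : -1;
    int c = cellof[i];
    int cc[3] = {c / (nc * nc), (c / nc) % nc, c % nc};
    double bnd = (dir > 0 ? cc[axis] + 1 : cc[axis]) * cellL;
    cell_remove(i);
    x[3 * i + axis] = bnd;
    cc[axis] += dir;
    if (cc[axis] >= nc) { cc[axis] = 0; x[3 * i + axis] -= L; }
    if (cc[axis] < 0) { cc[axis] = nc - 1; x[3 * i + axis] += L; }
    cell_insert_at(i, (cc[0] * nc + cc[1]) * nc + cc[2]);
  }

  void schedule_all_for(int i) {
    // pairs with particles in the 27 neighbouring cells
    int c = cellof[i];
    int cz = c % nc, cy = (c / nc) % nc, cx = c / (nc * nc);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int nx = (cx + dx + nc) % nc, ny = (cy + dy + nc) % nc,
              nz = (cz + dz + nc) % nc;
          int cidx = (nx * nc + ny) * nc + nz;
          for (int j = head[cidx]; j >= 0; j = nxt[j]) {
            if (j == i) continue;
            advance(j, now);
            predict_pair(i, j);
          }
        }
    predict_cell(i);
  }

  // apply an impulse along the centre line changing the relative normal
  // velocity from vn to vn_new (equal unit masses, reduced mass 1/2)
  void apply_normal(int i, int j, const double* nhat, double vn, double vn_new,
                    double r_evt) {
    double dv = 0.5 * (vn_new - vn);
    for (int k = 0; k < 3; ++k) {
      v[3 * i + k] += dv * nhat[k];
      v[3 * j + k] -= dv * nhat[k];
    }
    virial += 0.5 * (vn_new - vn) * r_evt;
  }

  // process one pair event; returns event label (1 core, 2 entry, 3 escape,
  // 4 interior bounce)
  int do_pair(int i, int j) {
    double r[3], w[3];
    relpos(i, j, r);
    for (int k = 0; k < 3; ++k) w[k] = v[3 * i + k] - v[3 * j + k];
    double rr = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
    double nhat[3] = {r[0] / rr, r[1] / rr, r[2] / rr};
    double vn = w[0] * nhat[0] + w[1] * nhat[1] + w[2] * nhat[2];
    double sig = R[i] + R[j];
    double rw = (1.0 + delta) * sig;
    int label;
    if (!well) {
      apply_normal(i, j, nhat, vn, -vn, rr);
      label = 1;
    } else if (!bonded(i, j)) {
      // well entry: radial speed-up, KE_rel gains u  (vn' ^2 = vn^2 + 4u)
      double vn_new = -std::sqrt(vn * vn + 4.0 * u);
      apply_normal(i, j, nhat, vn, vn_new, rr);
      bonds.insert(key(i, j));
      label = 2;
    } else if (rr < 0.5 * (sig + rw)) {
      // core collision (distance closer to sigma than to the well edge)
      apply_normal(i, j, nhat, vn, -vn, rr);
      label = 1;
    } else {
      // well-exit attempt: escape iff radial KE (mu vn^2/2, mu=1/2) > u
      if (vn * vn > 4.0 * u) {
        double vn_new = std::sqrt(vn * vn - 4.0 * u);
        apply_normal(i, j, nhat, vn, vn_new, rr);
        bonds.erase(key(i, j));
        label = 3;
      } else {
        apply_normal(i, j, nhat, vn, -vn, rr);
        label = 4;
      }
    }
    ++n_pair_events;
    return label;
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < 3 * N; ++i) ke += 0.5 * v[i] * v[i];
    return ke;
  }
  double potential() const { return -u * (double)bonds.size(); }

  void init_cells() {
    double maxR = 0;
    for (double r : R) maxR = std::max(maxR, r);
    double range = (well ? (1.0 + delta) : 1.0) * 2.0 * maxR;
    nc = (int)std::floor(L / range);
    if (nc < 3) nc = 3;          // fall back: minimum-image still valid
    if (nc > 40) nc = 40;
    cellL = L / nc;
    head.assign(nc * nc * nc, -1);
    nxt.assign(N, -1);
    cellof.assign(N, -1);
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 3; ++k) x[3 * i + k] = wrap(x[3 * i + k]);
      cell_insert(i);
    }
  }

  void init_bonds() {
    bonds.clear();
    if (!well) return;
    double r[3];
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        relpos(i, j, r);
        double rr = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
        if (rr < (1.0 + delta) * (R[i] + R[j])) bonds.insert(key(i, j));
      }
  }

  void build_queue() {
    pq = std::priority_queue<Event>();
    for (int i = 0; i < N; ++i) advance(i, now);
    for (int i = 0; i < N; ++i) {
      // schedule each pair once (from the lower index) plus cell crossings
      int c = cellof[i];
      int cz = c % nc, cy = (c / nc) % nc, cx = c / (nc * nc);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int nx = (cx + dx + nc) % nc, ny = (cy + dy + nc) % nc,
                nz = (cz + dz + nc) % nc;
            int cidx = (nx * nc + ny) * nc + nz;
            for (int j = head[cidx]; j >= 0; j = nxt[j])
              if (j > i) predict_pair(i, j);
          }
      predict_cell(i);
    }
  }

  // run until n_events pair events have been processed
  void run(long long n_events) {
    long long done = 0;
    long long guard = 0;
    long long guard_max = 400LL * n_events + 1000000LL;
    while (done < n_events) {
      if (pq.empty()) stop("event queue exhausted");
      if (++guard > guard_max) stop("event budget exceeded (stalled queue)");
      Event e = pq.top();
      pq.pop();
      if (e.t < now - 1e-9) stop("event-time ordering violation");
      bool valid = (e.ci == cnt[e.i]) &&
                   (e.kind == 1 || e.cj == cnt[e.j]);
      if (!valid) continue;
      double t_evt = std::max(e.t, now);
      now = t_evt;
      if (e.kind == 1) {
        advance(e.i, now);
        do_cell_cross(e.i, e.j);
        ++cnt[e.i];
        schedule_all_for(e.i);
      } else {
        advance(e.i, now);
        advance(e.j, now);
        do_pair(e.i, e.j);
        ++cnt[e.i];
        ++cnt[e.j];
        schedule_all_for(e.i);
        schedule_all_for(e.j);
        ++done;
      }
    }
    for (int i = 0; i < N; ++i) advance(i, now);
  }
};

Sim make_sim(NumericVector radii, NumericMatrix pos, NumericMatrix vel,
             double L, double u, double delta) {
  Sim s;
  s.N = radii.size();
  s.L = L;
  s.u = u;
  s.delta = delta;
  s.well = (u > 0);
  s.R.assign(radii.begin(), radii.end());
  s.x.resize(3 * s.N);
  s.v.resize(3 * s.N);
  s.tlast.assign(s.N, 0.0);
  s.cnt.assign(s.N, 0u);
  for (int i = 0; i < s.N; ++i)
    for (int k = 0; k < 3; ++k) {
      s.x[3 * i + k] = pos(i, k);
      s.v[3 * i + k] = vel(i, k);
    }
  s.init_cells();
  s.init_bonds();
  s.build_queue();
  return s;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_edmd(NumericVector radii, NumericMatrix pos, NumericMatrix vel,
                  double L, double u, double delta, double n_events) {
  Sim s = make_sim(radii, pos, vel, L, u, delta);
  double e0 = s.kinetic() + s.potential();
  s.run((long long)n_events);
  double e1 = s.kinetic() + s.potential();
  NumericMatrix opos(s.N, 3), ovel(s.N, 3);
  for (int i = 0; i < s.N; ++i)
    for (int k = 0; k < 3; ++k) {
      opos(i, k) = s.wrap(s.x[3 * i + k]);
      ovel(i, k) = s.v[3 * i + k];
    }
  return List::create(_["positions"] = opos, _["velocities"] = ovel,
                      _["time"] = s.now, _["energy_initial"] = e0,
                      _["energy_final"] = e1, _["kinetic"] = s.kinetic(),
                      _["potential"] = s.potential(),
                      _["n_bonds"] = (double)s.bonds.size(),
                      _["virial"] = s.virial,
                      _["n_pair_events"] = (double)s.n_pair_events);
}

// [[Rcpp::export]]
int cpp_count_overlaps(NumericVector radii, NumericMatrix pos, double L,
                       double tol = 1e-9) {
  int N = radii.size(), bad = 0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = pos(i, k) - pos(j, k);
        d -= L * std::round(d / L);
        r2 += d * d;
      }
      double sig = radii[i] + radii[j];
      if (r2 < (sig - tol) * (sig - tol)) ++bad;
    }
  return bad;
}

// Iterative overlap relaxation: radii are inflated stepwise from a dilute
// start; after each inflation, overlapping pairs are pushed apart along
// their centre line until the configuration is overlap-free at full size.
// [[Rcpp::export]]
List cpp_relax_configuration(NumericVector radii, double L, int max_sweeps) {
  int N = radii.size();
  NumericMatrix pos(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) = R::unif_rand() * L;
  double f = 0.2;
  int total_sweeps = 0;
  std::vector<double> Rf(N);
  while (true) {
    for (int i = 0; i < N; ++i) Rf[i] = f * radii[i];
    // push-apart sweeps at scale f
    bool clean = false;
    for (int sweep = 0; sweep < 2000; ++sweep) {
      if (++total_sweeps > max_sweeps)
        stop("overlap relaxation failed (jamming at scale %f)", f);
      int nover = 0;
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          double d[3], r2 = 0;
          for (int k = 0; k < 3; ++k) {
            double dd = pos(i, k) - pos(j, k);
            dd -= L * std::round(dd / L);
            d[k] = dd;
            r2 += dd * dd;
          }
          double sig = Rf[i] + Rf[j];
          if (r2 < sig * sig) {
            ++nover;
            double rr = std::sqrt(r2);
            if (rr < 1e-12) {
              d[0] = 1e-6 * (1 + i); d[1] = 0; d[2] = 0; rr = d[0];
            }
            double push = 0.5 * (sig - rr) * 1.05 + 1e-12;
            for (int k = 0; k < 3; ++k) {
              double nk = d[k] / rr;
              pos(i, k) += push * nk;
              pos(j, k) -= push * nk;
            }
          }
        }
      if (nover == 0) { clean = true; break; }
    }
    if (!clean) stop("overlap relaxation failed to converge at scale %f", f);
    if (f >= 1.0) break;
    f = std::min(1.0, f * 1.04);
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      double a = pos(i, k);
      a -= L * std::floor(a / L);
      if (a >= L || a < 0) a = 0;
      pos(i, k) = a;
    }
  return List::create(_["positions"] = pos, _["sweeps"] = total_sweeps);
}

// Histogram of scaled pair separations s = r / sigma_ij, normalised by the
// ideal-gas expectation so that the result is a radial distribution
// function in scaled units (exact for monodisperse systems, a
// sigma_ij^3-weighted analogue for polydisperse ones).
// [[Rcpp::export]]
List cpp_pair_distribution(NumericVector radii, NumericMatrix pos, double L,
                           double smax, int nbins) {
  int N = radii.size();
  std::vector<double> counts(nbins, 0.0);
  double V = L * L * L;
  double ds = smax / nbins;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = pos(i, k) - pos(j, k);
        d -= L * std::round(d / L);
        r2 += d * d;
      }
      double sig = radii[i] + radii[j];
      double s = std::sqrt(r2) / sig;
      if (s < smax) counts[(int)(s / ds)] += 1.0;
    }
  // ideal normalisation per bin: sum over pairs of (4 pi/3)(s2^3-s1^3)
  // sigma_ij^3 / V
  double sumsig3 = 0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double sig = radii[i] + radii[j];
      sumsig3 += sig * sig * sig;
    }
  NumericVector g(nbins), smid(nbins);
  for (int b = 0; b < nbins; ++b) {
    double s1 = b * ds, s2 = (b + 1) * ds;
    double ideal = (4.0 * M_PI / 3.0) * (s2 * s2 * s2 - s1 * s1 * s1) *
                   sumsig3 / V;
    smid[b] = 0.5 * (s1 + s2);
    g[b] = (ideal > 0) ? counts[b] / ideal : 0.0;
  }
  return List::create(_["s"] = smid, _["g"] = g);
}

// Effective (measurable) structure factor from a stack of configurations.
// q-vectors are commensurate with the box: q = 2 pi n / L with integer n;
// the caller passes the requested |n|^2 shells. For each shell all integer
// directions are enumerated and at most ndir_max are used (deterministic
// stride). Amplitudes f_i(q) = V_i * 3 (sin(qR) - qR cos(qR)) / (qR)^3.
//   S_M(q) = < |sum_i f_i e^{i q.r_i}|^2 > / sum_i f_i^2
// [[Rcpp::export]]
List cpp_effective_sq(NumericVector radii, NumericVector pos_stack,
                      int n_config, double L, IntegerVector nsq_shells,
                      int ndir_max) {
  int N = radii.size();
  int nsh = nsq_shells.size();
  NumericVector qout(nsh), sout(nsh);
  IntegerVector ndirs(nsh);
  std::vector<double> Vp(N);
  for (int i = 0; i < N; ++i)
    Vp[i] = (4.0 * M_PI / 3.0) * radii[i] * radii[i] * radii[i];
  for (int sh = 0; sh < nsh; ++sh) {
    int m = nsq_shells[sh];
    if (m < 1) stop("q below 2*pi/L rejected");
    int nmax = (int)std::floor(std::sqrt((double)m) + 1e-9);
    // enumerate half-space integer vectors with |n|^2 == m
    std::vector<std::array<int, 3>> dirs;
    for (int nx = 0; nx <= nmax; ++nx)
      for (int ny = (nx == 0 ? 0 : -nmax); ny <= nmax; ++ny)
        for (int nz = ((nx == 0 && ny == 0) ? 1 : -nmax); nz <= nmax; ++nz)
          if (nx * nx + ny * ny + nz * nz == m)
            dirs.push_back({nx, ny, nz});
    if (dirs.empty()) stop("no lattice vectors with |n|^2 = %d", m);
    int stride = std::max(1, (int)(dirs.size() / (size_t)ndir_max));
    double q = 2.0 * M_PI * std::sqrt((double)m) / L;
    // per-particle amplitudes at this q
    std::vector<double> f(N);
    double sumf2 = 0;
    for (int i = 0; i < N; ++i) {
      double xr = q * radii[i];
      double amp = (xr < 1e-3)
                       ? 1.0 - xr * xr / 10.0
                       : 3.0 * (std::sin(xr) - xr * std::cos(xr)) / (xr * xr * xr);
      f[i] = Vp[i] * amp;
      sumf2 += f[i] * f[i];
    }
    double acc = 0;
    int used = 0;
    for (size_t di = 0; di < dirs.size(); di += stride) {
      double kx = 2.0 * M_PI * dirs[di][0] / L;
      double ky = 2.0 * M_PI * dirs[di][1] / L;
      double kz = 2.0 * M_PI * dirs[di][2] / L;
      for (int c = 0; c < n_config; ++c) {
        const double* p = &pos_stack[(size_t)c * 3 * N];
        double re = 0, im = 0;
        for (int i = 0; i < N; ++i) {
          double ph = kx * p[3 * i] + ky * p[3 * i + 1] + kz * p[3 * i + 2];
          re += f[i] * std::cos(ph);
          im += f[i] * std::sin(ph);
        }
        acc += re * re + im * im;
      }
      ++used;
    }
    qout[sh] = q;
    sout[sh] = acc / ((double)used * n_config * sumf2);
    ndirs[sh] = used;
  }
  return List::create(_["q"] = qout, _["S"] = sout, _["n_dirs"] = ndirs);
}
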