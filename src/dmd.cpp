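// Event-driven molecular dynamics for stepwise (hard-sphere / square-well)
// pair potentials in a cubic periodic box.
//
// Correctness design: the next-event prediction for a pair is a pure function
// of the two particles' states (position-at-last-update, update time,
// velocity).  Particle state changes only at velocity-changing events and at
// per-particle "resync" events whose times are themselves pure functions of
// state.  Consequently the brute-force engine (fresh all-pairs scan at every
// step, no queue, no cells) and the optimized engine (binary heap with lazy
// invalidation + cell lists) perform identical floating-point arithmetic and
// generate bit-identical event sequences and final states.
//
// Minimum-image validity: a predicted root is only accepted if it occurs
// before the next resync of both particles.  Resyncs fire after a particle
// travels h = 0.45*(L/2 - range), which guarantees the nearest image chosen
// at prediction time is still the colliding image at contact
// (range + 2h < L/2).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// event types
enum { EV_CORE = 0, EV_IN = 1, EV_OUT = 2, EV_BOUNCE = 3,
       EV_CROSS = 8, EV_RESYNC = 9 };

struct Ev {
  double t;
  int type;        // EV_CORE / EV_IN / EV_OUT (pair), EV_CROSS, EV_RESYNC
  int i, j;        // pair indices (i < j); for CROSS j = axis; unused for RESYNC
  int bidx;        // boundary index into radii; for CROSS: direction +-1
  uint32_t ci, cj; // state counters at scheduling time
};

// deterministic ordering: time, then type, then indices
static inline bool ev_before(const Ev& a, const Ev& b) {
  if (a.t != b.t) return a.t < b.t;
  if (a.type != b.type) return a.type < b.type;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}
struct EvCmp { bool operator()(const Ev& a, const Ev& b) const {
  return ev_before(b, a); } };

class Engine {
public:
  int N;
  double L;
  bool use_cells;
  std::vector<double> rx, ry, rz, vx, vy, vz, t0;
  std::vector<uint32_t> cnt;
  std::vector<double> radii, radii2, depths; // radii[0] = sigma; depths per shell
  int nb;                                    // number of boundaries
  double range, h;

  // cells
  int nc;
  double cella;
  std::vector<int> cellid;                 // flat cell id per particle
  std::vector<std::vector<int> > members;  // particles per cell
  std::vector<int> mt;                     // 3*N next-boundary integers
  std::vector<int> ccoord;                 // 3*N cell coords

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;

  // accumulators
  double virial;
  double n_core, n_capture, n_escape, n_bounce, n_cross, n_resync;
  double steps;
  bool record;
  std::vector<double> log_t, log_i, log_j, log_type, log_b;

  Engine(NumericMatrix pos, NumericMatrix vel, double L_,
         NumericVector radii_, NumericVector depths_, double tstart,
         bool cells, bool record_) {
    N = pos.nrow();
    L = L_;
    use_cells = cells;
    record = record_;
    nb = radii_.size();
    radii.assign(radii_.begin(), radii_.end());
    depths.assign(depths_.begin(), depths_.end());
    radii2.resize(nb);
    for (int b = 0; b < nb; ++b) radii2[b] = radii[b] * radii[b];
    range = radii[nb - 1];
    if (L <= 2.05 * range)
      stop("box too small: L must exceed twice the interaction range");
    h = 0.45 * (0.5 * L - range);
    rx.resize(N); ry.resize(N); rz.resize(N);
    vx.resize(N); vy.resize(N); vz.resize(N);
    t0.assign(N, tstart);
    cnt.assign(N, 0u);
    for (int i = 0; i < N; ++i) {
      rx[i] = wrap(pos(i, 0)); ry[i] = wrap(pos(i, 1)); rz[i] = wrap(pos(i, 2));
      vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    }
    virial = 0.0;
    n_core = n_capture = n_escape = n_bounce = n_cross = n_resync = 0.0;
    steps = 0.0;
    if (use_cells) {
      nc = (int)std::floor(L / range);
      if (nc < 3) stop("internal error: cell engine requires >= 3 cells");
      cella = L / nc;
      mt.assign(3 * N, 0);
      ccoord.assign(3 * N, 0);
      build_cells();
      schedule_all();
    }
  }

  inline double wrap(double x) const {
    double y = x - L * std::floor(x / L);
    if (y >= L) y = 0.0;
    if (y < 0.0) y = 0.0;
    return y;
  }

  inline double speed(int i) const {
    return std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  }
  inline double next_resync(int i) const {
    double sp = speed(i);
    if (sp <= 0.0) return INF;
    return t0[i] + h / sp;
  }

  // ---- pure pair prediction ---------------------------------------------
  // Fills t/type/bidx of 'out'.  Returns false if no event before the
  // horizon.  Depends only on the two particles' states.
  bool predict(int i, int j, Ev& out) const {
    double tr = t0[i] > t0[j] ? t0[i] : t0[j];
    double dti = tr - t0[i], dtj = tr - t0[j];
    double dx = (rx[i] + vx[i] * dti) - (rx[j] + vx[j] * dtj);
    double dy = (ry[i] + vy[i] * dti) - (ry[j] + vy[j] * dtj);
    double dz = (rz[i] + vz[i] * dti) - (rz[j] + vz[j] * dtj);
    dx -= L * std::nearbyint(dx / L);
    dy -= L * std::nearbyint(dy / L);
    dz -= L * std::nearbyint(dz / L);
    double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
    double A = dvx * dvx + dvy * dvy + dvz * dvz;
    if (A <= 0.0) return false;
    double B = dx * dvx + dy * dvy + dz * dvz;
    double C = dx * dx + dy * dy + dz * dz;
    double best = INF;
    int btype = -1, bb = -1;
    for (int b = 0; b < nb; ++b) {
      double d2 = radii2[b];
      double rel = C - d2;
      bool outside = (std::fabs(rel) <= 1e-9 * d2) ? (B > 0.0) : (rel > 0.0);
      if (outside) {
        if (B < 0.0) {
          double disc = B * B - A * rel;
          if (disc > 0.0) {
            double s = (-B - std::sqrt(disc)) / A;
            if (s >= 0.0 && tr + s < best) {
              best = tr + s; btype = (b == 0) ? EV_CORE : EV_IN; bb = b;
            }
          }
        }
      } else {
        if (b == 0)
          stop("state corruption: pair inside hard core");
        double disc = B * B - A * rel;  // rel < 0 so disc > 0
        double s = (-B + std::sqrt(disc)) / A;
        if (s >= 0.0 && tr + s < best) { best = tr + s; btype = EV_OUT; bb = b; }
      }
    }
    if (btype < 0) return false;
    double horizon = next_resync(i);
    double hj = next_resync(j);
    if (hj < horizon) horizon = hj;
    if (best > horizon) return false;
    out.t = best; out.type = btype; out.i = i; out.j = j; out.bidx = bb;
    out.ci = cnt[i]; out.cj = cnt[j];
    return true;
  }

  // potential value in the region just inside / outside boundary b
  inline double u_inner(int b) const { return depths[b - 1]; }
  inline double u_outer(int b) const { return (b == nb - 1) ? 0.0 : depths[b]; }

  // ---- event application -------------------------------------------------
  void advance_particle(int i, double t) {
    double dt = t - t0[i];
    rx[i] = wrap(rx[i] + vx[i] * dt);
    ry[i] = wrap(ry[i] + vy[i] * dt);
    rz[i] = wrap(rz[i] + vz[i] * dt);
    t0[i] = t;
  }

  // returns actually applied type (EV_OUT may become EV_BOUNCE)
  int apply_pair(const Ev& e) {
    int i = e.i, j = e.j;
    advance_particle(i, e.t);
    advance_particle(j, e.t);
    double dx = rx[i] - rx[j], dy = ry[i] - ry[j], dz = rz[i] - rz[j];
    dx -= L * std::nearbyint(dx / L);
    dy -= L * std::nearbyint(dy / L);
    dz -= L * std::nearbyint(dz / L);
    double d2m = dx * dx + dy * dy + dz * dz;
    double d2 = radii2[e.bidx];
    if (std::fabs(d2m - d2) > 1e-6 * (d2 > 1.0 ? d2 : 1.0))
      stop("state corruption: pair not at event boundary");
    double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
    double B = dx * dvx + dy * dvy + dz * dvz;
    double fac;  // delta v_i = fac * dr
    int applied = e.type;
    if (e.type == EV_CORE) {
      fac = -B / d2m;
    } else {
      double du = (e.type == EV_IN) ? (u_inner(e.bidx) - u_outer(e.bidx))
                                    : (u_outer(e.bidx) - u_inner(e.bidx));
      double dist = std::sqrt(d2m);
      double vr = B / dist;
      double vr2p = vr * vr - 4.0 * du;   // mu = m/2, m = 1
      if (vr2p > 0.0) {
        double vrp = (vr >= 0.0 ? 1.0 : -1.0) * std::sqrt(vr2p);
        fac = (vrp - vr) / (2.0 * dist);
      } else {
        fac = -B / d2m;                   // elastic bounce off the step
        applied = EV_BOUNCE;
      }
    }
    double ivx = fac * dx, ivy = fac * dy, ivz = fac * dz;
    vx[i] += ivx; vy[i] += ivy; vz[i] += ivz;
    vx[j] -= ivx; vy[j] -= ivy; vz[j] -= ivz;
    virial += ivx * dx + ivy * dy + ivz * dz;
    cnt[i]++; cnt[j]++;
    switch (applied) {
      case EV_CORE:   n_core += 1.0; break;
      case EV_IN:     n_capture += 1.0; break;
      case EV_OUT:    n_escape += 1.0; break;
      case EV_BOUNCE: n_bounce += 1.0; break;
    }
    if (record) {
      log_t.push_back(e.t); log_i.push_back(i + 1); log_j.push_back(j + 1);
      log_type.push_back(applied); log_b.push_back(e.bidx);
    }
    return applied;
  }

  void apply_resync(int i, double t) {
    advance_particle(i, t);
    cnt[i]++;
    n_resync += 1.0;
  }

  // ---- cells -------------------------------------------------------------
  inline int flat(int cx, int cy, int cz) const {
    return (cz * nc + cy) * nc + cx;
  }
  void reset_crossing_targets(int i) {
    // particle state freshly wrapped at t0[i]
    double r[3] = { rx[i], ry[i], rz[i] };
    double v[3] = { vx[i], vy[i], vz[i] };
    for (int d = 0; d < 3; ++d) {
      int cd = (int)std::floor(r[d] / cella);
      if (cd >= nc) cd = nc - 1;
      if (cd < 0) cd = 0;
      ccoord[3 * i + d] = cd;
      if (v[d] > 0.0) mt[3 * i + d] = cd + 1;
      else mt[3 * i + d] = cd;  // v <= 0 (v == 0 gives INF time below)
    }
  }
  // earliest cell crossing for particle i: fills t and axis
  bool next_crossing(int i, double& tc, int& axis) const {
    double r[3] = { rx[i], ry[i], rz[i] };
    double v[3] = { vx[i], vy[i], vz[i] };
    tc = INF; axis = -1;
    for (int d = 0; d < 3; ++d) {
      if (v[d] == 0.0) continue;
      double tt = t0[i] + (mt[3 * i + d] * cella - r[d]) / v[d];
      if (tt < tc) { tc = tt; axis = d; }
    }
    return axis >= 0;
  }
  void place_in_cells(int i) {
    int id = flat(ccoord[3 * i], ccoord[3 * i + 1], ccoord[3 * i + 2]);
    cellid[i] = id;
    members[id].push_back(i);
  }
  void remove_from_cells(int i) {
    std::vector<int>& m = members[cellid[i]];
    for (size_t k = 0; k < m.size(); ++k)
      if (m[k] == i) { m[k] = m.back(); m.pop_back(); break; }
  }
  void build_cells() {
    cellid.assign(N, -1);
    members.assign(nc * nc * nc, std::vector<int>());
    for (int i = 0; i < N; ++i) {
      reset_crossing_targets(i);
      place_in_cells(i);
    }
  }
  template <class F>
  void for_neighbors(int i, F fun) const {
    int cx = ccoord[3 * i], cy = ccoord[3 * i + 1], cz = ccoord[3 * i + 2];
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int nx = (cx + ox + nc) % nc;
          int ny = (cy + oy + nc) % nc;
          int nz = (cz + oz + nc) % nc;
          const std::vector<int>& m = members[flat(nx, ny, nz)];
          for (size_t k = 0; k < m.size(); ++k)
            if (m[k] != i) fun(m[k]);
        }
  }

  // ---- heap scheduling ----------------------------------------------------
  void push_pair(int i, int j) {
    if (i > j) { int tmp = i; i = j; j = tmp; }
    Ev e;
    if (predict(i, j, e)) heap.push(e);
  }
  void push_crossing(int i) {
    double tc; int axis;
    if (next_crossing(i, tc, axis)) {
      Ev e; e.t = tc; e.type = EV_CROSS; e.i = i; e.j = axis;
      double v = (axis == 0 ? vx[i] : (axis == 1 ? vy[i] : vz[i]));
      e.bidx = v > 0.0 ? 1 : -1;
      e.ci = cnt[i]; e.cj = 0u;
      heap.push(e);
    }
  }
  void push_resync(int i) {
    double tr = next_resync(i);
    if (tr < INF) {
      Ev e; e.t = tr; e.type = EV_RESYNC; e.i = i; e.j = 0; e.bidx = 0;
      e.ci = cnt[i]; e.cj = 0u;
      heap.push(e);
    }
  }
  void repredict(int i) {
    for_neighbors(i, [&](int j) { push_pair(i, j); });
  }
  // after crossing axis d in direction dir, only the far plane of cells
  // becomes newly adjacent; existing pair events stay valid (purity) and
  // stale ones are refreshed at resyncs
  void repredict_plane(int i, int d, int dir) {
    int c[3] = { ccoord[3 * i], ccoord[3 * i + 1], ccoord[3 * i + 2] };
    int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
    int fixed = (c[d] + 2 * dir + 2 * nc) % nc;
    for (int a1 = -1; a1 <= 1; ++a1)
      for (int a2 = -1; a2 <= 1; ++a2) {
        int cc[3];
        cc[d] = fixed;
        cc[o1] = (c[o1] + a1 + nc) % nc;
        cc[o2] = (c[o2] + a2 + nc) % nc;
        const std::vector<int>& m = members[flat(cc[0], cc[1], cc[2])];
        for (size_t k = 0; k < m.size(); ++k)
          if (m[k] != i) push_pair(i, m[k]);
      }
  }
  void schedule_all() {
    for (int i = 0; i < N; ++i) {
      for_neighbors(i, [&](int j) { if (j > i) push_pair(i, j); });
      push_crossing(i);
      push_resync(i);
    }
  }
  void rebuild_heap() {
    heap = std::priority_queue<Ev, std::vector<Ev>, EvCmp>();
    schedule_all();
  }
  bool stale(const Ev& e) const {
    if (e.type == EV_CROSS || e.type == EV_RESYNC) return e.ci != cnt[e.i];
    return e.ci != cnt[e.i] || e.cj != cnt[e.j];
  }

  // next valid event via heap; returns false if none pending
  bool heap_peek(Ev& out) {
    while (!heap.empty()) {
      Ev e = heap.top();
      if (stale(e)) { heap.pop(); continue; }
      out = e;
      return true;
    }
    return false;
  }

  // next event via fresh brute-force scan (no caches)
  bool brute_next(Ev& out) const {
    Ev best; best.t = INF; best.type = 99; best.i = best.j = 0; best.bidx = 0;
    bool found = false;
    Ev cand;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        if (predict(i, j, cand) && (!found || ev_before(cand, best))) {
          best = cand; found = true;
        }
    for (int i = 0; i < N; ++i) {
      double tr = next_resync(i);
      if (tr < INF) {
        cand.t = tr; cand.type = EV_RESYNC; cand.i = i; cand.j = 0;
        cand.bidx = 0; cand.ci = cnt[i]; cand.cj = 0u;
        if (!found || ev_before(cand, best)) { best = cand; found = true; }
      }
    }
    if (!found) return false;
    out = best;
    return true;
  }

  // process internal events strictly before text; afterwards all particle
  // trajectories are valid through text
  void run_until(double text, double max_steps) {
    while (true) {
      Ev e;
      bool have = use_cells ? heap_peek(e) : brute_next(e);
      if (!have || e.t >= text) return;
      if (use_cells) heap.pop();
      steps += 1.0;
      if (steps > max_steps) stop("max_events exceeded");
      if (e.type == EV_RESYNC) {
        apply_resync(e.i, e.t);
        if (use_cells) {
          reset_crossing_targets(e.i);
          remove_from_cells(e.i); place_in_cells(e.i);
          push_crossing(e.i); push_resync(e.i);
          repredict(e.i);
        }
      } else if (e.type == EV_CROSS) {
        // bookkeeping only: no kinematic state change
        n_cross += 1.0;
        int i = e.i, d = e.j, dir = e.bidx;
        repredict_plane(i, d, dir);
        remove_from_cells(i);
        ccoord[3 * i + d] = (ccoord[3 * i + d] + dir + nc) % nc;
        mt[3 * i + d] += dir;
        place_in_cells(i);
        push_crossing(i);
      } else {
        apply_pair(e);
        if (use_cells) {
          int ij[2] = { e.i, e.j };
          for (int k = 0; k < 2; ++k) {
            int p = ij[k];
            reset_crossing_targets(p);
            remove_from_cells(p); place_in_cells(p);
            push_crossing(p); push_resync(p);
          }
          repredict(e.i); repredict(e.j);
        }
      }
      if (use_cells && heap.size() > (size_t)(200 * N + 10000))
        rebuild_heap();
    }
  }

  // advance every particle's stored state to time t (state change!)
  void sync_all(double t) {
    for (int i = 0; i < N; ++i) { advance_particle(i, t); cnt[i]++; }
    if (use_cells) { build_cells(); rebuild_heap(); }
  }

  NumericMatrix positions_at(double t) const {
    NumericMatrix out(N, 3);
    for (int i = 0; i < N; ++i) {
      double dt = t - t0[i];
      out(i, 0) = wrap(rx[i] + vx[i] * dt);
      out(i, 1) = wrap(ry[i] + vy[i] * dt);
      out(i, 2) = wrap(rz[i] + vz[i] * dt);
    }
    return out;
  }
  NumericMatrix velocities() const {
    NumericMatrix out(N, 3);
    for (int i = 0; i < N; ++i) {
      out(i, 0) = vx[i]; out(i, 1) = vy[i]; out(i, 2) = vz[i];
    }
    return out;
  }
};

// minimum-image pair histogram with uniform bins on [0, rmax)
static void accumulate_histogram(const NumericMatrix& pos, double L,
                                 int nbins, double rmax,
                                 std::vector<double>& counts) {
  int n = pos.nrow();
  double binw = rmax / nbins;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rmax) {
        int b = (int)(r / binw);
        if (b >= 0 && b < nbins) counts[b] += 1.0;
      }
    }
}

// [[Rcpp::export(name = ".dmd_run")]]
List dmd_run(NumericMatrix pos, NumericMatrix vel, double L,
             NumericVector radii, NumericVector depths,
             double t_start, double t_end,
             NumericVector snapshot_times,
             NumericVector rescale_times, double rescale_kT,
             bool use_cells, double max_steps, bool record_events,
             int rdf_nbins, double rdf_rmax, bool keep_snapshots) {
  Engine eng(pos, vel, L, radii, depths, t_start, use_cells, record_events);

  std::vector<double> rdf_counts;
  if (rdf_nbins > 0) rdf_counts.assign(rdf_nbins, 0.0);
  List snaps;
  int n_snap_taken = 0;

  // merge external actions (0 = snapshot, 1 = rescale), then final time
  int is = 0, ir = 0;
  int ns = snapshot_times.size(), nr = rescale_times.size();
  while (true) {
    double ts = is < ns ? snapshot_times[is] : INF;
    double tr = ir < nr ? rescale_times[ir] : INF;
    double text = std::min(std::min(ts, tr), t_end);
    eng.run_until(text, max_steps);
    if (text == INF) break;
    if (ts <= tr && ts <= t_end && is < ns) {
      NumericMatrix p = eng.positions_at(ts);
      if (rdf_nbins > 0)
        accumulate_histogram(p, L, rdf_nbins, rdf_rmax, rdf_counts);
      if (keep_snapshots) snaps.push_back(p);
      n_snap_taken++;
      is++;
      continue;
    }
    if (tr <= t_end && ir < nr) {
      eng.sync_all(tr);
      // zero total momentum, then rescale kinetic energy to 1.5 N kT
      double mx = 0, my = 0, mz = 0;
      for (int i = 0; i < eng.N; ++i) { mx += eng.vx[i]; my += eng.vy[i]; mz += eng.vz[i]; }
      mx /= eng.N; my /= eng.N; mz /= eng.N;
      double ke = 0;
      for (int i = 0; i < eng.N; ++i) {
        eng.vx[i] -= mx; eng.vy[i] -= my; eng.vz[i] -= mz;
        ke += eng.vx[i] * eng.vx[i] + eng.vy[i] * eng.vy[i] + eng.vz[i] * eng.vz[i];
      }
      ke *= 0.5;
      if (ke > 0) {
        double s = std::sqrt(1.5 * eng.N * rescale_kT / ke);
        for (int i = 0; i < eng.N; ++i) {
          eng.vx[i] *= s; eng.vy[i] *= s; eng.vz[i] *= s;
        }
      }
      if (eng.use_cells) eng.rebuild_heap();
      ir++;
      continue;
    }
    break;  // reached t_end
  }
  // final sync (no counter semantics needed beyond this point)
  NumericMatrix fpos = eng.positions_at(t_end);
  NumericMatrix fvel = eng.velocities();

  List out = List::create(
      _["positions"] = fpos, _["velocities"] = fvel, _["time"] = t_end,
      _["virial"] = eng.virial,
      _["counts"] = NumericVector::create(
          _["core"] = eng.n_core, _["capture"] = eng.n_capture,
          _["escape"] = eng.n_escape, _["bounce"] = eng.n_bounce,
          _["cross"] = eng.n_cross, _["resync"] = eng.n_resync,
          _["steps"] = eng.steps),
      _["n_snapshots"] = n_snap_taken);
  if (rdf_nbins > 0) out["rdf_counts"] = NumericVector(rdf_counts.begin(), rdf_counts.end());
  if (keep_snapshots) out["snapshots"] = snaps;
  if (record_events) {
    int ne = eng.log_t.size();
    NumericMatrix evm(ne, 5);
    for (int k = 0; k < ne; ++k) {
      evm(k, 0) = eng.log_t[k]; evm(k, 1) = eng.log_i[k];
      evm(k, 2) = eng.log_j[k]; evm(k, 3) = eng.log_type[k];
      evm(k, 4) = eng.log_b[k];
    }
    colnames(evm) = CharacterVector::create("time", "i", "j", "type", "boundary");
    out["events"] = evm;
  }
  return out;
}

// [[Rcpp::export(name = ".dmd_predict_pair")]]
List dmd_predict_pair(NumericVector r1, NumericVector v1,
                      NumericVector r2, NumericVector v2,
                      double L, NumericVector radii) {
  NumericMatrix pos(2, 3), vel(2, 3);
  for (int d = 0; d < 3; ++d) {
    pos(0, d) = r1[d]; pos(1, d) = r2[d];
    vel(0, d) = v1[d]; vel(1, d) = v2[d];
  }
  NumericVector depths(std::max((int)radii.size() - 1, 0));
  Engine eng(pos, vel, L, radii, depths, 0.0, false, false);
  eng.h = INF;  // no horizon for the single-pair query
  Ev e;
  if (!eng.predict(0, 1, e))
    return List::create(_["time"] = R_PosInf, _["type"] = "none",
                        _["boundary"] = NA_REAL);
  const char* tn = e.type == EV_CORE ? "core_collision"
                   : (e.type == EV_IN ? "shell_cross_in" : "shell_cross_out");
  return List::create(_["time"] = e.t, _["type"] = tn,
                      _["boundary"] = radii[e.bidx]);
}

// [[Rcpp::export(name = ".dmd_resolve_pair")]]
List dmd_resolve_pair(NumericVector dr, NumericVector v1, NumericVector v2,
                      int bidx, std::string kind,
                      NumericVector radii, NumericVector depths) {
  // dr = r_i - r_j at the boundary (no wrapping applied)
  int nb = radii.size();
  double d2m = dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2];
  double dvx = v1[0] - v2[0], dvy = v1[1] - v2[1], dvz = v1[2] - v2[2];
  double B = dr[0] * dvx + dr[1] * dvy + dr[2] * dvz;
  double fac;
  std::string applied = kind;
  if (kind == "core_collision") {
    fac = -B / d2m;
  } else {
    double ui = depths[bidx - 1];
    double uo = (bidx == nb - 1) ? 0.0 : depths[bidx];
    double du = (kind == "shell_cross_in") ? (ui - uo) : (uo - ui);
    double dist = std::sqrt(d2m);
    double vr = B / dist;
    double vr2p = vr * vr - 4.0 * du;
    if (vr2p > 0.0) {
      double vrp = (vr >= 0.0 ? 1.0 : -1.0) * std::sqrt(vr2p);
      fac = (vrp - vr) / (2.0 * dist);
    } else {
      fac = -B / d2m;
      applied = "bounce";
    }
  }
  NumericVector w1 = clone(v1), w2 = clone(v2);
  for (int d = 0; d < 3; ++d) {
    w1[d] += fac * dr[d];
    w2[d] -= fac * dr[d];
  }
  return List::create(_["v1"] = w1, _["v2"] = w2, _["outcome"] = applied,
                      _["virial"] = fac * d2m);
}

// [[Rcpp::export(name = ".pair_histogram")]]
NumericVector pair_histogram(NumericMatrix pos, double L, int nbins,
                             double rmax) {
  std::vector<double> counts(nbins, 0.0);
  accumulate_histogram(pos, L, nbins, rmax, counts);
  return NumericVector(counts.begin(), counts.end());
}

// [[Rcpp::export(name = ".min_pair_distance")]]
double min_pair_distance(NumericMatrix pos, double L) {
  int n = pos.nrow();
  double best = INF;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// total potential energy of a configuration under a stepwise potential
// [[Rcpp::export(name = ".potential_energy")]]
double potential_energy(NumericMatrix pos, double L, NumericVector radii,
                        NumericVector depths) {
  int n = pos.nrow();
  int nb = radii.size();
  double pe = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= radii[nb - 1]) continue;
      // r below sigma would be a corrupted state; report +Inf
      if (r < radii[0]) return INF;
      for (int b = 1; b < nb; ++b)
        if (r <= radii[b]) { pe += depths[b - 1]; break; }
    }
  return pe;
}
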