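// Core flocking engine: topological neighbour search on a uniform grid and
// the fixed-step state update (social forces, speed control, banked turns).
//
// All state is SI: positions m, speeds m/s, forces N, angles rad.
// The update is single-threaded and iterates birds in index order, so a run
// is bit-reproducible given (state, params, seed).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

constexpr double kGravity = 9.81; // m s^-2

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 normalized() const {
    double n = norm();
    return n > 0 ? Vec3(x / n, y / n, z / n) : Vec3(0, 0, 0);
  }
};

// splitmix64: tiny counter-based generator; the only stochastic draw during a
// run is the escape direction for exactly coincident positions.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  Vec3 unit_vector() {
    // Marsaglia rejection on the unit sphere
    for (;;) {
      double u = 2.0 * runif() - 1.0, v = 2.0 * runif() - 1.0;
      double s = u * u + v * v;
      if (s < 1.0 && s > 0.0) {
        double f = 2.0 * std::sqrt(1.0 - s);
        return {u * f, v * f, 1.0 - 2.0 * s};
      }
    }
  }
};

// Uniform-grid exact k-nearest-neighbour index. Cells are scanned in
// expanding Chebyshev shells; a shell level L guarantees every point within
// distance L*cell is seen, so the k-th candidate distance certifies the
// result. Ties broken by lower bird index.
class NeighborGrid {
 public:
  void build(const std::vector<Vec3>& pos, double cell) {
    n_ = static_cast<int>(pos.size());
    cell_ = cell;
    lo_ = Vec3(std::numeric_limits<double>::max(),
               std::numeric_limits<double>::max(),
               std::numeric_limits<double>::max());
    Vec3 hi(-lo_.x, -lo_.y, -lo_.z);
    for (const Vec3& p : pos) {
      lo_.x = std::min(lo_.x, p.x); lo_.y = std::min(lo_.y, p.y); lo_.z = std::min(lo_.z, p.z);
      hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
    }
    nx_ = std::max(1, static_cast<int>(std::floor((hi.x - lo_.x) / cell_)) + 1);
    ny_ = std::max(1, static_cast<int>(std::floor((hi.y - lo_.y) / cell_)) + 1);
    nz_ = std::max(1, static_cast<int>(std::floor((hi.z - lo_.z) / cell_)) + 1);
    cix_.assign(n_, 0); ciy_.assign(n_, 0); ciz_.assign(n_, 0);
    head_.assign(static_cast<size_t>(nx_) * ny_ * nz_, -1);
    next_.assign(n_, -1);
    for (int i = 0; i < n_; ++i) {
      int cx = clampi(static_cast<int>(std::floor((pos[i].x - lo_.x) / cell_)), 0, nx_ - 1);
      int cy = clampi(static_cast<int>(std::floor((pos[i].y - lo_.y) / cell_)), 0, ny_ - 1);
      int cz = clampi(static_cast<int>(std::floor((pos[i].z - lo_.z) / cell_)), 0, nz_ - 1);
      cix_[i] = cx; ciy_[i] = cy; ciz_[i] = cz;
      size_t c = cellIndex(cx, cy, cz);
      next_[i] = head_[c];
      head_[c] = i;
    }
  }

  // k nearest neighbours of `focal` (excluding it), optionally restricted to
  // a view cone of half-angle with cos(half_angle) = cos_half around
  // `forward`. Results ascending by (distance, index).
  void query(const std::vector<Vec3>& pos, int focal, int k,
             bool use_fov, const Vec3& forward, double cos_half,
             std::vector<int>& out_idx, std::vector<double>& out_d) const {
    out_idx.clear(); out_d.clear();
    if (k <= 0) return;
    const Vec3 p = pos[focal];
    // (dist2, index) candidate heap kept as sorted insertion into small array
    std::vector<std::pair<double, int>> best;
    best.reserve(k + 1);
    int max_shell = std::max(std::max(nx_, ny_), nz_);
    for (int L = 1; L <= max_shell + 1; ++L) {
      scanShell(pos, focal, L - 1, p, use_fov, forward, cos_half, k, best);
      // cells at Chebyshev distance >= L lie at least (L-1)*cell away, so
      // after scanning shells 0..L-1 the result is certified within that
      // radius
      if (static_cast<int>(best.size()) >= k) {
        double dk = std::sqrt(best[k - 1].first);
        if (dk <= cell_ * (L - 1)) break;
      }
    }
    int m = std::min<int>(k, best.size());
    for (int i = 0; i < m; ++i) {
      out_idx.push_back(best[i].second);
      out_d.push_back(std::sqrt(best[i].first));
    }
  }

 private:
  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }
  size_t cellIndex(int cx, int cy, int cz) const {
    return (static_cast<size_t>(cz) * ny_ + cy) * nx_ + cx;
  }

  void scanShell(const std::vector<Vec3>& pos, int focal, int L, const Vec3& p,
                 bool use_fov, const Vec3& forward, double cos_half, int k,
                 std::vector<std::pair<double, int>>& best) const {
    int cx = cix_[focal], cy = ciy_[focal], cz = ciz_[focal];
    for (int dz = -L; dz <= L; ++dz) {
      int z = cz + dz; if (z < 0 || z >= nz_) continue;
      for (int dy = -L; dy <= L; ++dy) {
        int y = cy + dy; if (y < 0 || y >= ny_) continue;
        for (int dx = -L; dx <= L; ++dx) {
          // only the outer shell: interior cells were scanned at lower L
          if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != L) continue;
          int x = cx + dx; if (x < 0 || x >= nx_) continue;
          for (int j = head_[cellIndex(x, y, z)]; j != -1; j = next_[j]) {
            if (j == focal) continue;
            Vec3 dvec = pos[j] - p;
            if (use_fov) {
              double dn = dvec.norm();
              if (dn > 0 && dvec.dot(forward) < cos_half * dn) continue;
            }
            double d2 = dvec.dot(dvec);
            std::pair<double, int> cand(d2, j);
            if (static_cast<int>(best.size()) == k && !(cand < best.back())) continue;
            best.insert(std::upper_bound(best.begin(), best.end(), cand), cand);
            if (static_cast<int>(best.size()) > k) best.pop_back();
          }
        }
      }
    }
  }

  int n_ = 0, nx_ = 1, ny_ = 1, nz_ = 1;
  double cell_ = 1.0;
  Vec3 lo_;
  std::vector<int> cix_, ciy_, ciz_, next_;
  std::vector<int64_t> dummy_;
  std::vector<int> head_;
};

// separation weight: 1 inside the hard sphere, decaying to 0 at r_sep
inline double sepWeight(double d, double r_h, double r_sep, bool smooth) {
  if (d <= r_h) return 1.0;
  if (d >= r_sep) return 0.0;
  double u = (r_sep - d) / (r_sep - r_h);
  if (!smooth) return u;
  return u * u * (3.0 - 2.0 * u); // smoothstep option
}

struct Params {
  double r_h, r_sep, w_sep, w_align, w_cohere;
  int k_avoid, k_topo;
  double fov_half; // rad; >= pi disables the filter
  double cruise, mass, tau;
  double roll_in, roll_out, max_roll, pitch_gain;
  double centrality_gain, w_noise, reaction_time, cruise_spread;
  bool smooth_sep, topo_mix, align_velocity, cohere_spring;
};

Params readParams(const List& par) {
  Params q;
  q.r_h = as<double>(par["rH"]);
  q.r_sep = as<double>(par["rSep"]);
  q.w_sep = as<double>(par["wSep"]);
  q.w_align = as<double>(par["wAlign"]);
  q.w_cohere = as<double>(par["wCohere"]);
  q.k_avoid = as<int>(par["kAvoid"]);
  q.k_topo = as<int>(par["kTopo"]);
  q.fov_half = as<double>(par["fovHalfAngle"]);
  q.cruise = as<double>(par["cruiseSpeed"]);
  q.mass = as<double>(par["mass"]);
  q.tau = as<double>(par["speedTau"]);
  q.roll_in = as<double>(par["rollInRate"]);
  q.roll_out = as<double>(par["rollOutRate"]);
  q.max_roll = as<double>(par["maxRoll"]);
  q.pitch_gain = as<double>(par["pitchGain"]);
  q.centrality_gain = as<double>(par["centralityGain"]);
  q.w_noise = as<double>(par["wNoise"]);
  q.reaction_time = as<double>(par["reactionTime"]);
  q.topo_mix = as<bool>(par["kTopoMix"]);
  q.align_velocity = as<bool>(par["alignVelocity"]);
  q.cruise_spread = as<double>(par["cruiseSpread"]);
  q.cohere_spring = as<bool>(par["cohereSpring"]);
  q.smooth_sep = as<std::string>(par["sepDecay"]) == "smoothstep";
  return q;
}

// Horizontal-projection body frame: ez0 = world up projected off ex,
// ey0 = ez0 x ex the sideward axis (right-handed frame).
inline void levelFrame(const Vec3& ex, Vec3& ey0, Vec3& ez0) {
  Vec3 up(0, 0, 1);
  Vec3 e = up - ex * ex.dot(up);
  double n = e.norm();
  if (n < 1e-8) { // flying straight up/down: fall back to world x as reference
    Vec3 ref(1, 0, 0);
    e = ref - ex * ex.dot(ref);
    n = e.norm();
  }
  ez0 = e * (1.0 / n);
  ey0 = ez0.cross(ex);
}

} // namespace

// [[Rcpp::export(name = ".knn_all_cpp")]]
IntegerMatrix knn_all_cpp(NumericMatrix positions, int k, double cell_hint) {
  int n = positions.nrow();
  if (k < 1 || k > n - 1) stop("k must be in [1, N-1]");
  std::vector<Vec3> pos(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = Vec3(positions(i, 0), positions(i, 1), positions(i, 2));
    if (!std::isfinite(pos[i].x) || !std::isfinite(pos[i].y) || !std::isfinite(pos[i].z))
      stop("non-finite coordinate at row %d", i + 1);
  }
  NeighborGrid grid;
  grid.build(pos, cell_hint);
  IntegerMatrix out(n, k);
  std::vector<int> idx; std::vector<double> d;
  Vec3 fwd(1, 0, 0);
  for (int i = 0; i < n; ++i) {
    grid.query(pos, i, k, false, fwd, -1.0, idx, d);
    for (int j = 0; j < k; ++j) out(i, j) = idx[j] + 1; // 1-based for R
  }
  return out;
}

// Advance the flock n_steps of dt, recording every record_every steps
// (step 0, i.e. the initial state, is recorded when record_initial).
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericMatrix positions, NumericMatrix headings,
                  NumericVector speeds, NumericVector banks,
                  List par, double dt, int n_steps, int record_every,
                  bool record_initial, double rng_seed, double bird_seed) {
  const int n = positions.nrow();
  if (n < 2) stop("a flock needs at least 2 birds");
  Params q = readParams(par);
  if (q.k_topo > n - 1) q.k_topo = n - 1;
  if (q.k_avoid > n - 1) q.k_avoid = n - 1;
  const int k_query = std::max(q.k_avoid, q.k_topo);
  const bool use_fov = q.fov_half < M_PI - 1e-12;
  const double cos_half = std::cos(q.fov_half);

  std::vector<Vec3> pos(n), ex(n);
  std::vector<double> spd(n), bank(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = Vec3(positions(i, 0), positions(i, 1), positions(i, 2));
    ex[i] = Vec3(headings(i, 0), headings(i, 1), headings(i, 2)).normalized();
    spd[i] = speeds[i];
    bank[i] = banks[i];
  }
  SplitMix64 rng(static_cast<uint64_t>(rng_seed));
  int coincident_events = 0;

  // quenched individual variation: each bird's preferred cruise speed is a
  // fixed offset derived from the world seed (not the segment stream), so
  // it is identical across consecutive simulation segments
  std::vector<double> cruise_i(n, q.cruise);
  if (q.cruise_spread > 0) {
    SplitMix64 bird_rng(static_cast<uint64_t>(bird_seed));
    for (int i = 0; i < n; ++i)
      cruise_i[i] = q.cruise * (1.0 + q.cruise_spread * (2.0 * bird_rng.runif() - 1.0));
  }

  const int n_rec = (record_initial ? 1 : 0) + n_steps / record_every;
  NumericVector rec_t(n_rec);
  // [T, N, 3] arrays stored column-major as T*N*3 vectors
  NumericVector rec_pos(static_cast<R_xlen_t>(n_rec) * n * 3);
  NumericVector rec_fwd(static_cast<R_xlen_t>(n_rec) * n * 3);
  int rec_i = 0;
  auto record = [&](double t) {
    rec_t[rec_i] = t;
    for (int i = 0; i < n; ++i) {
      R_xlen_t base = rec_i + static_cast<R_xlen_t>(i) * n_rec;
      R_xlen_t stride = static_cast<R_xlen_t>(n_rec) * n;
      rec_pos[base] = pos[i].x; rec_pos[base + stride] = pos[i].y; rec_pos[base + 2 * stride] = pos[i].z;
      rec_fwd[base] = ex[i].x;  rec_fwd[base + stride] = ex[i].y;  rec_fwd[base + 2 * stride] = ex[i].z;
    }
    ++rec_i;
  };
  if (record_initial) record(0.0);

  NeighborGrid grid;
  std::vector<int> nb; std::vector<double> nd;
  std::vector<Vec3> new_ex(n), force(n);
  std::vector<double> f_fwd(n);

  // social forces are re-evaluated at the behavioural reaction rate, not
  // every integration step; phases are staggered so birds do not react in
  // lock-step. Between reactions the social force is held constant.
  int react_every = std::max(1, static_cast<int>(std::lround(q.reaction_time / dt)));
  std::vector<int> phase(n, 0);
  if (react_every > 1)
    for (int i = 0; i < n; ++i)
      phase[i] = static_cast<int>(rng.next() % static_cast<uint64_t>(react_every));

  for (int s = 1; s <= n_steps; ++s) {
    // grid cell sized to keep a handful of birds per cell
    Vec3 mn = pos[0], mx = pos[0];
    for (const Vec3& p : pos) {
      mn.x = std::min(mn.x, p.x); mn.y = std::min(mn.y, p.y); mn.z = std::min(mn.z, p.z);
      mx.x = std::max(mx.x, p.x); mx.y = std::max(mx.y, p.y); mx.z = std::max(mx.z, p.z);
    }
    double vol = std::max((mx.x - mn.x) * (mx.y - mn.y) * (mx.z - mn.z), 1e-9);
    double cell = std::max(0.05, 1.5 * std::cbrt(vol / n));
    grid.build(pos, cell);

    for (int i = 0; i < n; ++i) {
      if (react_every > 1 && (s - 1) % react_every != phase[i] && s > 1) {
        f_fwd[i] = force[i].dot(ex[i]);
        continue;
      }
      grid.query(pos, i, k_query, use_fov, ex[i], cos_half, nb, nd);
      const int m = static_cast<int>(nb.size());
      const int m_avoid = std::min(q.k_avoid, m);
      // topological range "6 or 7": with kTopoMix each bird redraws its
      // alignment/cohesion range between k_topo-1 and k_topo per reaction
      int k_topo_i = q.k_topo;
      if (q.topo_mix && q.k_topo > 1 && (rng.next() & 1)) --k_topo_i;
      const int m_topo = std::min(k_topo_i, m);

      // separation: mean over avoided neighbours of g(d) * unit(focal - nb)
      Vec3 f_sep;
      if (m_avoid > 0) {
        for (int j = 0; j < m_avoid; ++j) {
          double d = nd[j];
          double g = sepWeight(d, q.r_h, q.r_sep, q.smooth_sep);
          if (g <= 0.0) continue;
          Vec3 u;
          if (d > 0) {
            u = (pos[i] - pos[nb[j]]) * (1.0 / d);
          } else {
            u = rng.unit_vector();
            ++coincident_events;
          }
          f_sep += u * g;
        }
        f_sep = f_sep * (q.w_sep / m_avoid);
      }

      // alignment: velocity matching against the topological set (a
      // viscosity damping relative motion), or the pure heading form
      Vec3 f_ali;
      if (m_topo > 0) {
        if (q.align_velocity) {
          Vec3 mean_v;
          for (int j = 0; j < m_topo; ++j) mean_v += ex[nb[j]] * spd[nb[j]];
          mean_v = mean_v * (1.0 / m_topo);
          f_ali = (mean_v - ex[i] * spd[i]) * (q.w_align / q.cruise);
        } else {
          Vec3 mean_e;
          for (int j = 0; j < m_topo; ++j) mean_e += ex[nb[j]];
          double mn_ = mean_e.norm();
          if (mn_ > 1e-12) f_ali = (mean_e * (1.0 / mn_) - ex[i]) * q.w_align;
        }
      }

      // cohesion: unit vector toward the topological centroid, optionally
      // scaled by centrality (how one-sided the neighbour distribution is),
      // so attraction acts mainly on peripheral birds
      Vec3 f_coh;
      if (m_topo > 0) {
        Vec3 c, udir;
        for (int j = 0; j < m_topo; ++j) {
          c += pos[nb[j]];
          if (nd[j] > 0) udir += (pos[nb[j]] - pos[i]) * (1.0 / nd[j]);
        }
        c = c * (1.0 / m_topo);
        double theta = udir.norm() / m_topo; // 0 deep inside, ~1 at the border
        double scale = 1.0 - q.centrality_gain + q.centrality_gain * theta;
        Vec3 dvec = c - pos[i];
        double dn = dvec.norm();
        // spring form: attraction grows with the offset to the perceived
        // centre (N per metre), penalizing protrusions and stragglers;
        // unit form: constant-magnitude attraction
        if (q.cohere_spring) f_coh = dvec * (q.w_cohere * scale);
        else if (dn > 1e-12) f_coh = dvec * (q.w_cohere * scale / dn);
      }

      // behavioural noise: isotropic random force redrawn per reaction,
      // Weber-scaled by the distance to the closest neighbour (perceptual
      // error grows with the distance at which neighbours are tracked),
      // capped at the separation radius
      Vec3 f_noise;
      if (q.w_noise > 0) {
        double scale_d = (m > 0) ? std::min(nd[0], q.r_sep) : q.r_sep;
        f_noise = rng.unit_vector() * (q.w_noise * scale_d);
      }

      force[i] = f_sep + f_ali + f_coh + f_noise;
      f_fwd[i] = force[i].dot(ex[i]);
    }

    // state update (forces frozen for the step: explicit Euler)
    for (int i = 0; i < n; ++i) {
      Vec3 ey0, ez0;
      levelFrame(ex[i], ey0, ez0);
      double f_lat = force[i].dot(ey0);
      double f_up = force[i].dot(ez0);

      // banked turn: roll toward the angle where lateral lift balances the
      // lateral steering demand; asymmetric rate limits, clamped magnitude
      double target = std::atan2(f_lat, q.mass * kGravity);
      if (target > q.max_roll) target = q.max_roll;
      if (target < -q.max_roll) target = -q.max_roll;
      double delta = target - bank[i];
      double rate = (std::fabs(target) > std::fabs(bank[i])) ? q.roll_in : q.roll_out;
      double max_d = rate * dt;
      if (delta > max_d) delta = max_d;
      if (delta < -max_d) delta = -max_d;
      bank[i] += delta;

      // turning acceleration: lateral lift component g*tan(bank) plus the
      // vertical force component, with a level-flight pitch restoring term
      double sp = std::max(spd[i], 0.5);
      double a_lat = kGravity * std::tan(bank[i]);
      double a_up = f_up / q.mass - q.pitch_gain * sp * ex[i].z;
      Vec3 exn = ex[i] + (ey0 * a_lat + ez0 * a_up) * (dt / sp);
      new_ex[i] = exn.normalized();

      // speed relaxation to the individual cruise speed plus forward force
      spd[i] += dt * ((cruise_i[i] - spd[i]) / q.tau + f_fwd[i] / q.mass);
      if (spd[i] < 0.0) spd[i] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      ex[i] = new_ex[i];
      pos[i] += ex[i] * (spd[i] * dt);
      if (!std::isfinite(pos[i].x) || !std::isfinite(pos[i].y) || !std::isfinite(pos[i].z))
        stop("non-finite position for bird %d at step %d", i + 1, s);
    }
    if (s % record_every == 0) record(s * dt);
  }

  NumericMatrix out_pos(n, 3), out_ex(n, 3);
  NumericVector out_spd(n), out_bank(n);
  for (int i = 0; i < n; ++i) {
    out_pos(i, 0) = pos[i].x; out_pos(i, 1) = pos[i].y; out_pos(i, 2) = pos[i].z;
    out_ex(i, 0) = ex[i].x; out_ex(i, 1) = ex[i].y; out_ex(i, 2) = ex[i].z;
    out_spd[i] = spd[i]; out_bank[i] = bank[i];
  }
  rec_pos.attr("dim") = IntegerVector::create(n_rec, n, 3);
  rec_fwd.attr("dim") = IntegerVector::create(n_rec, n, 3);
  return List::create(
      _["times"] = rec_t, _["positions"] = rec_pos, _["forwards"] = rec_fwd,
      _["finalPositions"] = out_pos, _["finalHeadings"] = out_ex,
      _["finalSpeeds"] = out_spd, _["finalBanks"] = out_bank,
      _["coincidentEvents"] = coincident_events);
}
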