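// Capsule (spherocylinder) geometry in the plane, grid-hashed contact
// detection, and the iterative overlap-relaxation solver. These are the
// per-timestep hot loops; everything stochastic stays on the R side so the
// whole simulation is driven by R's RNG.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Minimum distance between two segments p1 +- (l1/2) u1 and p2 +- (l2/2) u2.
// Clamped closed-form solution (Ericson, Real-Time Collision Detection,
// restricted to 2D). Also reports the closest points.
static double seg_seg_distance(double p1x, double p1y, double u1x, double u1y,
                               double l1, double p2x, double p2y, double u2x,
                               double u2y, double l2, double &c1x, double &c1y,
                               double &c2x, double &c2y) {
  // endpoints
  double a1x = p1x - 0.5 * l1 * u1x, a1y = p1y - 0.5 * l1 * u1y;
  double a2x = p2x - 0.5 * l2 * u2x, a2y = p2y - 0.5 * l2 * u2y;
  double d1x = l1 * u1x, d1y = l1 * u1y; // direction a1 -> b1
  double d2x = l2 * u2x, d2y = l2 * u2y;
  double rx = a1x - a2x, ry = a1y - a2y;
  double A = d1x * d1x + d1y * d1y; // squared length seg 1
  double E = d2x * d2x + d2y * d2y;
  double F = d2x * rx + d2y * ry;
  double s = 0.0, t = 0.0;
  const double EPS = 1e-14;
  if (A <= EPS && E <= EPS) {
    s = t = 0.0;
  } else if (A <= EPS) {
    t = F / E;
    t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
  } else {
    double C = d1x * rx + d1y * ry;
    if (E <= EPS) {
      s = -C / A;
      s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
    } else {
      double B = d1x * d2x + d1y * d2y;
      double denom = A * E - B * B;
      if (denom > EPS) {
        s = (B * F - C * E) / denom;
        s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
      } else {
        s = 0.0; // parallel: pick an end, then re-derive s below
      }
      t = (B * s + F) / E;
      if (t < 0.0) {
        t = 0.0;
        s = -C / A;
        s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
      } else if (t > 1.0) {
        t = 1.0;
        s = (B - C) / A;
        s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
      }
    }
  }
  c1x = a1x + s * d1x;
  c1y = a1y + s * d1y;
  c2x = a2x + t * d2x;
  c2y = a2y + t * d2y;
  double dx = c1x - c2x, dy = c1y - c2y;
  return std::sqrt(dx * dx + dy * dy);
}

// [[Rcpp::export]]
double cpp_capsule_distance(NumericVector a, NumericVector b) {
  // a, b = c(x, y, ux, uy, length, radius)
  double c1x, c1y, c2x, c2y;
  for (int i = 0; i < 6; ++i)
    if (!R_finite(a[i]) || !R_finite(b[i]))
      stop("invalid geometry: non-finite capsule coordinates");
  double d = seg_seg_distance(a[0], a[1], a[2], a[3], a[4], b[0], b[1], b[2],
                              b[3], b[4], c1x, c1y, c2x, c2y);
  return d - (a[5] + b[5]);
}

struct GridHash {
  double h;     // bucket edge length
  double x0, y0;
  std::unordered_map<int64_t, std::vector<int>> buckets;
  int64_t key(int ix, int iy) const {
    return (static_cast<int64_t>(ix) << 32) ^
           (static_cast<int64_t>(iy) & 0xffffffffLL);
  }
  void build(const double *x, const double *y, int n, double cell) {
    h = cell;
    buckets.clear();
    x0 = 0.0;
    y0 = 0.0;
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor((x[i] - x0) / h);
      int iy = (int)std::floor((y[i] - y0) / h);
      buckets[key(ix, iy)].push_back(i);
    }
  }
};

// Candidate pairs whose surface separation can be <= tol: centers closer
// than (l_i + l_j)/2 + r_i + r_j + tol <= grid cell edge, so scanning the
// 3x3 neighborhood of each bucket is exhaustive.
static void candidate_pairs(const double *x, const double *y,
                            const double *len, const double *rad, int n,
                            double tol, std::vector<std::pair<int, int>> &out) {
  out.clear();
  if (n < 2) return;
  double maxreach = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.5 * len[i] + rad[i];
    if (e > maxreach) maxreach = e;
  }
  double cell = 2.0 * maxreach + tol + 1e-9;
  GridHash g;
  g.build(x, y, n, cell);
  for (auto &kv : g.buckets) {
    int ix = (int)(kv.first >> 32);
    int iy = (int)(kv.first & 0xffffffffLL);
    // sign restore for iy (stored as low 32 bits)
    iy = (int)((int32_t)iy);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = g.buckets.find(g.key(ix + dx, iy + dy));
        if (it == g.buckets.end()) continue;
        const std::vector<int> &a = kv.second;
        const std::vector<int> &b = it->second;
        bool same = (dx == 0 && dy == 0);
        for (size_t ii = 0; ii < a.size(); ++ii) {
          for (size_t jj = same ? ii + 1 : 0; jj < b.size(); ++jj) {
            int i = a[ii], j = b[jj];
            if (!same && i >= j) continue; // count each unordered pair once
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            double lim = 0.5 * (len[i] + len[j]) + rad[i] + rad[j] + tol;
            if (ddx * ddx + ddy * ddy <= lim * lim)
              out.push_back(std::make_pair(i, j));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_build_contacts(NumericVector x, NumericVector y, NumericVector angle,
                        NumericVector len, NumericVector rad, double tol) {
  int n = x.size();
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(angle[i]) ||
        !R_finite(len[i]))
      stop("invalid geometry: non-finite cell state at index %d", i + 1);
  std::vector<double> ux(n), uy(n);
  for (int i = 0; i < n; ++i) {
    ux[i] = std::cos(angle[i]);
    uy[i] = std::sin(angle[i]);
  }
  std::vector<std::pair<int, int>> cand;
  candidate_pairs(REAL(x), REAL(y), REAL(len), REAL(rad), n, tol, cand);
  std::vector<int> pi, pj;
  std::vector<double> sep;
  double c1x, c1y, c2x, c2y;
  for (auto &pr : cand) {
    int i = pr.first, j = pr.second;
    double d = seg_seg_distance(x[i], y[i], ux[i], uy[i], len[i], x[j], y[j],
                                ux[j], uy[j], len[j], c1x, c1y, c2x, c2y) -
               (rad[i] + rad[j]);
    if (d <= tol) {
      pi.push_back(i + 1);
      pj.push_back(j + 1);
      sep.push_back(d);
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["sep"] = wrap(sep));
}

// Iterated sequential pairwise overlap projection with a torque-like axis
// correction. Cells in overlap are pushed apart along the line joining the
// closest core points; the displacement is damped (viscous drag) and a small
// rotation proportional to the torque of the push about the cell center is
// applied. Neighbor lists are rebuilt with a skin every `rebuild_every`
// iterations. Converged when max overlap <= resid_tol.
// [[Rcpp::export]]
List cpp_relax(NumericVector x_, NumericVector y_, NumericVector angle_,
               NumericVector len, NumericVector rad, double damp,
               double rot_gain, double resid_tol, int max_iter, double skin,
               int rebuild_every, Nullable<LogicalVector> awake_ = R_NilValue) {
  NumericVector x = clone(x_), y = clone(y_), angle = clone(angle_);
  int n = x.size();
  // Motion originates from cells flagged awake (typically: cells that
  // elongated this step). A pair is only projected if either member is
  // awake; any cell that gets pushed wakes up, so stress propagates through
  // force chains within the sweep loop while the static colony core is
  // skipped. With awake_ = NULL every cell is awake (full relaxation).
  std::vector<char> awake(n, 1);
  if (awake_.isNotNull()) {
    LogicalVector aw(awake_);
    for (int i = 0; i < n; ++i) awake[i] = aw[i] ? 1 : 0;
  }
  std::vector<double> ux(n), uy(n);
  auto refresh_axes = [&]() {
    for (int i = 0; i < n; ++i) {
      ux[i] = std::cos(angle[i]);
      uy[i] = std::sin(angle[i]);
    }
  };
  refresh_axes();
  std::vector<std::pair<int, int>> pairs, active;
  double max_ov = 0.0;
  int it = 0;
  double c1x, c1y, c2x, c2y;
  // Active set: only pairs already within `active_cut` of contact take part
  // in the projection sweeps; the set is refreshed (with a full candidate
  // scan) every `rebuild_every` sweeps, so pairs drifting into contact are
  // picked up at the next refresh (or next timestep) at worst.
  const double active_cut = 0.15;
  int since_rebuild = rebuild_every; // force a rebuild on the first sweep
  for (it = 0; it < max_iter; ++it) {
    bool fresh = since_rebuild >= rebuild_every;
    if (fresh) {
      since_rebuild = 0;
      refresh_axes();
      candidate_pairs(REAL(x), REAL(y), REAL(len), REAL(rad), n, skin, pairs);
      active.clear();
      for (auto &pr : pairs) {
        int i = pr.first, j = pr.second;
        double d = seg_seg_distance(x[i], y[i], ux[i], uy[i], len[i], x[j],
                                    y[j], ux[j], uy[j], len[j], c1x, c1y,
                                    c2x, c2y) -
                   (rad[i] + rad[j]);
        if (d <= active_cut) active.push_back(pr);
      }
    }
    ++since_rebuild;
    max_ov = 0.0;
    for (auto &pr : active) {
      int i = pr.first, j = pr.second;
      if (!awake[i] && !awake[j]) continue;
      double d = seg_seg_distance(x[i], y[i], ux[i], uy[i], len[i], x[j], y[j],
                                  ux[j], uy[j], len[j], c1x, c1y, c2x, c2y) -
                 (rad[i] + rad[j]);
      double ov = -d;
      if (ov <= resid_tol) continue;
      if (ov > max_ov) max_ov = ov;
      // push direction: from j's closest point toward i's closest point
      double nx = c1x - c2x, ny = c1y - c2y;
      double nn = std::sqrt(nx * nx + ny * ny);
      if (nn < 1e-12) { // coincident cores: separate along perpendiculars
        nx = uy[i];
        ny = -ux[i];
        nn = 1.0;
      }
      nx /= nn;
      ny /= nn;
      double push = 0.5 * damp * ov;
      x[i] += push * nx;
      y[i] += push * ny;
      x[j] -= push * nx;
      y[j] -= push * ny;
      awake[i] = 1;
      awake[j] = 1;
      if (rot_gain > 0.0) {
        // torque of the push about each center; inertia ~ (l/2)^2/3 + r^2
        double aix = c1x - x[i], aiy = c1y - y[i];
        double ajx = c2x - x[j], ajy = c2y - y[j];
        double Ii = len[i] * len[i] / 12.0 + rad[i] * rad[i];
        double Ij = len[j] * len[j] / 12.0 + rad[j] * rad[j];
        double dth_i = rot_gain * push * (aix * ny - aiy * nx) / Ii;
        double dth_j = rot_gain * push * (-(ajx * ny - ajy * nx)) / Ij;
        const double cap = 0.05;
        if (dth_i > cap) dth_i = cap; else if (dth_i < -cap) dth_i = -cap;
        if (dth_j > cap) dth_j = cap; else if (dth_j < -cap) dth_j = -cap;
        angle[i] += dth_i;
        angle[j] += dth_j;
        // small-angle rotation of the cached axes (|dth| <= 0.05 so the
        // 3rd-order series is exact to ~1e-7); axes are re-derived from the
        // accumulated angles at every neighbor-list refresh
        double ci = 1.0 - 0.5 * dth_i * dth_i;
        double si = dth_i * (1.0 - dth_i * dth_i / 6.0);
        double cj = 1.0 - 0.5 * dth_j * dth_j;
        double sj = dth_j * (1.0 - dth_j * dth_j / 6.0);
        double nxi = ux[i] * ci - uy[i] * si;
        uy[i] = ux[i] * si + uy[i] * ci;
        ux[i] = nxi;
        double nxj = ux[j] * cj - uy[j] * sj;
        uy[j] = ux[j] * sj + uy[j] * cj;
        ux[j] = nxj;
      }
    }
    if (max_ov <= resid_tol) {
      // only trust convergence verified against a fresh neighbor scan:
      // pushes may have created overlaps outside the stale active set
      if (fresh) {
        ++it;
        break;
      }
      since_rebuild = rebuild_every;
    }
  }
  // final residual check against a fresh neighbor list
  refresh_axes();
  candidate_pairs(REAL(x), REAL(y), REAL(len), REAL(rad), n, 0.0, pairs);
  max_ov = 0.0;
  for (auto &pr : pairs) {
    int i = pr.first, j = pr.second;
    double d = seg_seg_distance(x[i], y[i], ux[i], uy[i], len[i], x[j], y[j],
                                ux[j], uy[j], len[j], c1x, c1y, c2x, c2y) -
               (rad[i] + rad[j]);
    if (-d > max_ov) max_ov = -d;
  }
  return List::create(_["x"] = x, _["y"] = y, _["angle"] = angle,
                      _["max_overlap"] = max_ov, _["iterations"] = it);
}

// FNV-1a 64-bit hash of a string, hex-encoded; used to stamp snapshots with
// a parameter fingerprint.
// [[Rcpp::export]]
std::string cpp_fnv1a(std::string s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
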