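#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic bidirectional streamline propagation through a voxel-wise
// multi-peak direction field.  Everything is in world mm; voxel lookup goes
// through the inverse affine (0-based indices, nearest voxel centre).
//
// Termination codes: 0 angle, 1 brain_boundary, 2 stop_mask, 3 max_steps,
// 4 no_peak.

struct Grid {
  int nx, ny, nz, k;
  const double *dirs;    // nx*ny*nz*3*k
  const double *values;  // nx*ny*nz*k
  const int *npeaks;     // nx*ny*nz
  const int *brain;      // nx*ny*nz
  std::vector<const int *> stops;
  const double *inv;     // 4x4 column-major world->voxel
};

static inline bool voxel_of(const Grid &g, const double p[3], int ijk[3]) {
  for (int r = 0; r < 3; ++r) {
    double x = g.inv[r] * p[0] + g.inv[4 + r] * p[1] + g.inv[8 + r] * p[2] +
               g.inv[12 + r];
    ijk[r] = (int)std::floor(x + 0.5);
  }
  return ijk[0] >= 0 && ijk[0] < g.nx && ijk[1] >= 0 && ijk[1] < g.ny &&
         ijk[2] >= 0 && ijk[2] < g.nz;
}

static inline int lin3(const Grid &g, const int ijk[3]) {
  return ijk[0] + g.nx * (ijk[1] + g.ny * ijk[2]);
}

// most-inline peak: maximise |d.m|; ties (<1e-9) resolved by rank order,
// which is PDF-value order (peaks are stored sorted by value descending)
static inline bool pick_peak(const Grid &g, const int ijk[3],
                             const double d[3], double out[3]) {
  int v3 = lin3(g, ijk);
  int np = g.npeaks[v3];
  if (np <= 0) return false;
  double best = -1.0;
  int besti = -1;
  double bdot = 0.0;
  for (int j = 0; j < np && j < g.k; ++j) {
    double m[3];
    bool ok = true;
    for (int c = 0; c < 3; ++c) {
      m[c] = g.dirs[ijk[0] +
                    g.nx * (ijk[1] + g.ny * ((long)ijk[2] +
                                             (long)g.nz * (c + 3 * j)))];
      if (!std::isfinite(m[c])) ok = false;
    }
    if (!ok) return false;  // NaN in the field: treat as untrackable voxel
    double dot = d[0] * m[0] + d[1] * m[1] + d[2] * m[2];
    double a = std::fabs(dot);
    if (a > best + 1e-9) {
      best = a;
      besti = j;
      bdot = dot;
      out[0] = m[0]; out[1] = m[1]; out[2] = m[2];
    }
  }
  if (besti < 0) return false;
  if (bdot < 0) { out[0] = -out[0]; out[1] = -out[1]; out[2] = -out[2]; }
  return true;
}

// march from `seed` along initial direction d0; returns termination code and
// appends visited points (seed excluded) to pts
static int march(const Grid &g, const double seed[3], const double d0[3],
                 double step, double cos_turn, int max_steps,
                 std::vector<double> &pts) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < max_steps; ++s) {
    int ijk[3];
    if (!voxel_of(g, p, ijk) || !g.brain[lin3(g, ijk)]) return 1;
    double m[3];
    if (!pick_peak(g, ijk, d, m)) return 4;
    double dot = d[0] * m[0] + d[1] * m[1] + d[2] * m[2];
    if (dot < cos_turn) return 0;  // would exceed the turn limit
    double q[3] = {p[0] + step * m[0], p[1] + step * m[1],
                   p[2] + step * m[2]};
    pts.push_back(q[0]); pts.push_back(q[1]); pts.push_back(q[2]);
    int qijk[3];
    bool in_grid = voxel_of(g, q, qijk);
    if (!in_grid || !g.brain[lin3(g, qijk)]) return 1;
    for (size_t t = 0; t < g.stops.size(); ++t)
      if (g.stops[t][lin3(g, qijk)]) return 2;
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    d[0] = m[0]; d[1] = m[1]; d[2] = m[2];
  }
  return 3;
}

// [[Rcpp::export(name = ".cpp_track")]]
List cpp_track(NumericVector dirs, NumericVector values, IntegerVector npeaks,
               IntegerVector brain, List stop_masks, NumericMatrix inv_affine,
               NumericMatrix seeds, double step, double max_turn,
               int max_steps, int min_points, bool per_peak) {
  IntegerVector dd = dirs.attr("dim");
  Grid g;
  g.nx = dd[0]; g.ny = dd[1]; g.nz = dd[2]; g.k = dd[4];
  g.dirs = REAL(dirs);
  g.values = REAL(values);
  g.npeaks = INTEGER(npeaks);
  g.brain = INTEGER(brain);
  for (int i = 0; i < stop_masks.size(); ++i) {
    IntegerVector m = stop_masks[i];
    g.stops.push_back(INTEGER(m));
  }
  g.inv = REAL(inv_affine);
  double cos_turn = std::cos(max_turn * M_PI / 180.0);

  std::vector<NumericMatrix> mats;
  std::vector<int> seed_idx, term_f, term_b;

  int nseed = seeds.nrow();
  for (int i = 0; i < nseed; ++i) {
    double seed[3] = {seeds(i, 0), seeds(i, 1), seeds(i, 2)};
    int ijk[3];
    if (!voxel_of(g, seed, ijk) || !g.brain[lin3(g, ijk)]) continue;
    int np = g.npeaks[lin3(g, ijk)];
    if (np <= 0) continue;
    int nlaunch = per_peak ? std::min(np, g.k) : 1;
    for (int j = 0; j < nlaunch; ++j) {
      double d0[3];
      bool ok = true;
      for (int c = 0; c < 3; ++c) {
        d0[c] = g.dirs[ijk[0] +
                       g.nx * (ijk[1] + g.ny * ((long)ijk[2] +
                                                (long)g.nz * (c + 3 * j)))];
        if (!std::isfinite(d0[c])) ok = false;
      }
      if (!ok) continue;
      std::vector<double> fwd, bwd;
      int tf = march(g, seed, d0, step, cos_turn, max_steps, fwd);
      double d0n[3] = {-d0[0], -d0[1], -d0[2]};
      int tb = march(g, seed, d0n, step, cos_turn, max_steps, bwd);
      int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
      int npts = nb + 1 + nf;
      if (npts < min_points) continue;
      NumericMatrix m(npts, 3);
      for (int r = 0; r < nb; ++r)          // backward half, reversed
        for (int c = 0; c < 3; ++c) m(r, c) = bwd[3 * (nb - 1 - r) + c];
      for (int c = 0; c < 3; ++c) m(nb, c) = seed[c];
      for (int r = 0; r < nf; ++r)
        for (int c = 0; c < 3; ++c) m(nb + 1 + r, c) = fwd[3 * r + c];
      mats.push_back(m);
      seed_idx.push_back(i + 1);
      term_f.push_back(tf);
      term_b.push_back(tb);
    }
  }
  int n = (int)mats.size();
  List points(n);
  for (int i = 0; i < n; ++i) points[i] = mats[i];
  return List::create(_["points"] = points,
                      _["seed"] = wrap(seed_idx),
                      _["term_forward"] = wrap(term_f),
                      _["term_backward"] = wrap(term_b));
}
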