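#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact parametric (Siddon-style) traversal of the segment p0 -> p1 through a
// regular axis-aligned voxel grid. Voxel (i,j,k) (0-based) occupies the
// half-open box [origin + i*spacing, origin + (i+1)*spacing) per axis.
// Boundary hits produce zero-length chords that are dropped; voxel membership
// of each chord is decided at the chord midpoint, which is deterministic for
// rays through faces/edges.

struct GridGeom {
  double org[3], sp[3];
  int dim[3];
};

static inline GridGeom make_geom(const NumericVector& origin,
                                 const NumericVector& spacing,
                                 const IntegerVector& dims) {
  GridGeom g;
  for (int a = 0; a < 3; ++a) {
    g.org[a] = origin[a];
    g.sp[a] = spacing[a];
    g.dim[a] = dims[a];
  }
  return g;
}

// Walk the in-grid portion of segment p0 + t*(p1-p0), t in [0,1].
// Calls visit(i, j, k, chord_len, t_entry, t_exit) per traversed voxel.
// Returns the parametric in-grid interval [tmin, tmax] (tmin > tmax when the
// segment misses the grid).
template <typename F>
static void walk_segment(const double* p0, const double* p1,
                         const GridGeom& g, F visit,
                         double* t_in = nullptr, double* t_out = nullptr) {
  double dir[3], L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    dir[a] = p1[a] - p0[a];
    L2 += dir[a] * dir[a];
  }
  double L = std::sqrt(L2);
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    double bmin = g.org[a], bmax = g.org[a] + g.sp[a] * g.dim[a];
    if (dir[a] == 0.0) {
      if (p0[a] < bmin || p0[a] >= bmax) { tmin = 1.0; tmax = 0.0; break; }
    } else {
      double ta = (bmin - p0[a]) / dir[a];
      double tb = (bmax - p0[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      tmin = std::max(tmin, ta);
      tmax = std::min(tmax, tb);
    }
  }
  if (t_in) *t_in = tmin;
  if (t_out) *t_out = tmax;
  if (!(tmax > tmin) || L == 0.0) return;

  // incremental boundary crossings per axis
  double tNext[3], tDelta[3];
  int stepDir[3];
  for (int a = 0; a < 3; ++a) {
    if (dir[a] == 0.0) {
      tNext[a] = R_PosInf; tDelta[a] = R_PosInf; stepDir[a] = 0;
    } else {
      stepDir[a] = dir[a] > 0 ? 1 : -1;
      tDelta[a] = g.sp[a] / std::fabs(dir[a]);
      double pos = p0[a] + tmin * dir[a];
      double f = (pos - g.org[a]) / g.sp[a];
      double cell = std::floor(f);
      double bound = dir[a] > 0 ? (cell + 1.0) : cell;
      tNext[a] = ((g.org[a] + bound * g.sp[a]) - p0[a]) / dir[a];
      if (tNext[a] <= tmin) tNext[a] += tDelta[a];
    }
  }
  double tCur = tmin;
  const double eps = 1e-12;
  while (tCur < tmax - eps) {
    double tStop = std::min(std::min(tNext[0], tNext[1]),
                            std::min(tNext[2], tmax));
    if (tStop > tCur + eps) {
      double tmid = 0.5 * (tCur + tStop);
      int idx[3];
      bool inside = true;
      for (int a = 0; a < 3; ++a) {
        double pos = p0[a] + tmid * dir[a];
        idx[a] = (int)std::floor((pos - g.org[a]) / g.sp[a]);
        if (idx[a] < 0 || idx[a] >= g.dim[a]) { inside = false; break; }
      }
      if (inside)
        visit(idx[0], idx[1], idx[2], (tStop - tCur) * L, tCur, tStop);
    }
    for (int a = 0; a < 3; ++a)
      if (tNext[a] <= tStop + eps) tNext[a] += tDelta[a];
    tCur = tStop;
  }
}

// [[Rcpp::export]]
List cpp_siddon_chords(NumericVector p0, NumericVector p1,
                       NumericVector origin, NumericVector spacing,
                       IntegerVector dims) {
  GridGeom g = make_geom(origin, spacing, dims);
  std::vector<int> vi, vj, vk;
  std::vector<double> len;
  double t_in, t_out;
  walk_segment(&p0[0], &p1[0], g,
               [&](int i, int j, int k, double l, double, double) {
                 vi.push_back(i); vj.push_back(j); vk.push_back(k);
                 len.push_back(l);
               },
               &t_in, &t_out);
  int n = (int)len.size();
  IntegerMatrix ijk(n, 3);
  NumericVector l(n);
  for (int r = 0; r < n; ++r) {
    ijk(r, 0) = vi[r]; ijk(r, 1) = vj[r]; ijk(r, 2) = vk[r];
    l[r] = len[r];
  }
  double L = 0.0;
  for (int a = 0; a < 3; ++a) L += (p1[a] - p0[a]) * (p1[a] - p0[a]);
  L = std::sqrt(L);
  double in_len = (t_out > t_in) ? (t_out - t_in) * L : 0.0;
  return List::create(_["ijk"] = ijk, _["length"] = l,
                      _["in_grid_length"] = in_len,
                      _["total_length"] = L);
}

// Water-equivalent pathlength from a common source point to each row of pts.
// Out-of-grid portions of each segment contribute with outside_density.
// [[Rcpp::export]]
NumericVector cpp_wepl_batch(NumericVector src, NumericMatrix pts,
                             NumericVector origin, NumericVector spacing,
                             IntegerVector dims, NumericVector density,
                             double outside_density) {
  GridGeom g = make_geom(origin, spacing, dims);
  int n = pts.nrow();
  int nx = g.dim[0], ny = g.dim[1];
  NumericVector out(n);
  double p0[3] = {src[0], src[1], src[2]};
  for (int r = 0; r < n; ++r) {
    double p1[3] = {pts(r, 0), pts(r, 1), pts(r, 2)};
    double wepl = 0.0, in_len = 0.0;
    walk_segment(p0, p1, g,
                 [&](int i, int j, int k, double l, double, double) {
                   wepl += l * density[i + nx * (j + (R_xlen_t)ny * k)];
                   in_len += l;
                 });
    double L = 0.0;
    for (int a = 0; a < 3; ++a) L += (p1[a] - p0[a]) * (p1[a] - p0[a]);
    L = std::sqrt(L);
    out[r] = wepl + (L - in_len) * outside_density;
  }
  return out;
}

// For each ray (src through a row of `through`, extended far enough to leave
// the grid): whether it traverses any TRUE voxel of `mask`, and the
// water-equivalent depth, measured from src, of the entry into the first and
// the exit from the last such voxel. Columns: hit (0/1), proximal, distal.
// [[Rcpp::export]]
NumericMatrix cpp_ray_mask_depths(NumericVector src, NumericMatrix through,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dims, NumericVector density,
                                  LogicalVector mask, double outside_density) {
  GridGeom g = make_geom(origin, spacing, dims);
  int n = through.nrow();
  int nx = g.dim[0], ny = g.dim[1];
  NumericMatrix out(n, 3);
  double p0[3] = {src[0], src[1], src[2]};

  // extend every ray beyond the farthest grid corner
  double far2 = 0.0;
  for (int c = 0; c < 8; ++c) {
    double d2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double corner = g.org[a] + ((c >> a) & 1) * g.sp[a] * g.dim[a];
      d2 += (corner - p0[a]) * (corner - p0[a]);
    }
    far2 = std::max(far2, d2);
  }
  double far = std::sqrt(far2) * 1.05 + 1.0;

  for (int r = 0; r < n; ++r) {
    double d[3], L = 0.0;
    for (int a = 0; a < 3; ++a) {
      d[a] = through(r, a) - p0[a];
      L += d[a] * d[a];
    }
    L = std::sqrt(L);
    if (L == 0.0) { out(r, 0) = 0; continue; }
    double p1[3];
    double scale = far / L;
    for (int a = 0; a < 3; ++a) p1[a] = p0[a] + d[a] * scale;

    bool hit = false;
    double prox = NA_REAL, dist = NA_REAL;
    double wepl = 0.0, geo = 0.0; // cumulative from src at current entry
    double t_in = 0.0;
    double segL = far;
    walk_segment(p0, p1, g,
                 [&](int i, int j, int k, double l, double ta, double tb) {
                   // out-of-grid gap before this chord
                   double gap = ta * segL - geo;
                   if (gap > 0) { wepl += gap * outside_density; geo = ta * segL; }
                   bool m = mask[i + nx * (j + (R_xlen_t)ny * k)];
                   if (m && !hit) { hit = true; prox = wepl; }
                   double rho = density[i + nx * (j + (R_xlen_t)ny * k)];
                   wepl += l * rho;
                   geo = tb * segL;
                   if (m) dist = wepl;
                 },
                 &t_in, nullptr);
    out(r, 0) = hit ? 1.0 : 0.0;
    out(r, 1) = prox;
    out(r, 2) = dist;
  }
  return out;
}

// Minimum Euclidean distance (2-D) from each point to a reference set, plus
// the index (1-based) of the nearest reference. Used for signed distances to
// the aperture edge on the collimator plane.
// [[Rcpp::export]]
List cpp_min_dist2(NumericMatrix points, NumericMatrix refs) {
  int n = points.nrow(), m = refs.nrow();
  NumericVector dmin(n);
  IntegerVector which(n);
  for (int r = 0; r < n; ++r) {
    double best = R_PosInf;
    int bi = NA_INTEGER;
    double px = points(r, 0), py = points(r, 1);
    for (int s = 0; s < m; ++s) {
      double dx = px - refs(s, 0), dy = py - refs(s, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = s + 1; }
    }
    dmin[r] = std::sqrt(best);
    which[r] = bi;
  }
  return List::create(_["dist"] = dmin, _["which"] = which);
}
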