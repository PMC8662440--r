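// Point-cloud primitives used by the R-level modules.
// All routines are deliberately dependency-free (plain Rcpp + STL): grids are
// uniform hash grids, the triangulation is incremental Bowyer-Watson.

#include <Rcpp.h>
#include <map>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one key
  auto enc = [](int v) -> int64_t { return (int64_t)(v + 1048576) & 0x1FFFFF; };
  return (enc(ix) << 42) | (enc(iy) << 21) | enc(iz);
}

struct Grid3 {
  double cs, x0, y0, z0;
  std::unordered_map<int64_t, std::vector<int>> cells;
  void build(const NumericVector& x, const NumericVector& y,
             const NumericVector& z, double cell) {
    cs = cell;
    x0 = *std::min_element(x.begin(), x.end());
    y0 = *std::min_element(y.begin(), y.end());
    z0 = *std::min_element(z.begin(), z.end());
    for (int i = 0; i < x.size(); ++i)
      cells[key(x[i], y[i], z[i])].push_back(i);
  }
  int64_t key(double x, double y, double z) const {
    return cell_key((int)std::floor((x - x0) / cs),
                    (int)std::floor((y - y0) / cs),
                    (int)std::floor((z - z0) / cs));
  }
};

} // namespace

// Mean distance to the k nearest neighbours of every point (3D).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericVector x, NumericVector y,
                                NumericVector z, int k) {
  const int n = x.size();
  NumericVector out(n);
  if (n <= 1) return out;
  if (k > n - 1) k = n - 1;

  // cell size targeting ~k points per cell
  double dx = std::max(1e-6, *std::max_element(x.begin(), x.end()) -
                                  *std::min_element(x.begin(), x.end()));
  double dy = std::max(1e-6, *std::max_element(y.begin(), y.end()) -
                                  *std::min_element(y.begin(), y.end()));
  double dz = std::max(1e-6, *std::max_element(z.begin(), z.end()) -
                                  *std::min_element(z.begin(), z.end()));
  double cs = std::cbrt(dx * dy * dz / n * (k + 1.0));
  cs = std::max(cs, 1e-4);

  Grid3 g;
  g.build(x, y, z, cs);

  for (int i = 0; i < n; ++i) {
    std::priority_queue<double> best; // max-heap of k smallest distances
    int ix = (int)std::floor((x[i] - g.x0) / cs);
    int iy = (int)std::floor((y[i] - g.y0) / cs);
    int iz = (int)std::floor((z[i] - g.z0) / cs);
    for (int ring = 0;; ++ring) {
      // points in the current shell of cells
      for (int ax = ix - ring; ax <= ix + ring; ++ax)
        for (int ay = iy - ring; ay <= iy + ring; ++ay)
          for (int az = iz - ring; az <= iz + ring; ++az) {
            if (ring > 0 && std::abs(ax - ix) != ring &&
                std::abs(ay - iy) != ring && std::abs(az - iz) != ring)
              continue; // interior cell, already visited
            auto it = g.cells.find(cell_key(ax, ay, az));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double d = std::sqrt((x[i] - x[j]) * (x[i] - x[j]) +
                                   (y[i] - y[j]) * (y[i] - y[j]) +
                                   (z[i] - z[j]) * (z[i] - z[j]));
              if ((int)best.size() < k) best.push(d);
              else if (d < best.top()) { best.pop(); best.push(d); }
            }
          }
      // all points within ring*cs of the query are guaranteed seen
      if ((int)best.size() == k && best.top() <= ring * cs) break;
      if (ring > 2 && (int)best.size() == k &&
          ring * cs > 3 * std::max({dx, dy, dz})) break; // safety
      if (ring * cs > 2 * std::max({dx, dy, dz}) + cs) break; // exhausted
    }
    double s = 0; int m = (int)best.size();
    while (!best.empty()) { s += best.top(); best.pop(); }
    out[i] = m > 0 ? s / m : 0.0;
  }
  return out;
}

// 2D DBSCAN. Neighbourhood counts include the point itself. Returns cluster
// labels 1..m, 0 for noise.
// [[Rcpp::export]]
IntegerVector cpp_dbscan2d(NumericVector x, NumericVector y, double eps,
                           int minpts) {
  const int n = x.size();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;

  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  double cs = eps;
  std::unordered_map<int64_t, std::vector<int>> cells;
  auto key = [&](double px, double py) {
    return cell_key((int)std::floor((px - x0) / cs),
                    (int)std::floor((py - y0) / cs), 0);
  };
  for (int i = 0; i < n; ++i) cells[key(x[i], y[i])].push_back(i);

  const double e2 = eps * eps;
  auto neighbours = [&](int i, std::vector<int>& out) {
    out.clear();
    int ix = (int)std::floor((x[i] - x0) / cs);
    int iy = (int)std::floor((y[i] - y0) / cs);
    for (int ax = ix - 1; ax <= ix + 1; ++ax)
      for (int ay = iy - 1; ay <= iy + 1; ++ay) {
        auto it = cells.find(cell_key(ax, ay, 0));
        if (it == cells.end()) continue;
        for (int j : it->second) {
          double d2 = (x[i] - x[j]) * (x[i] - x[j]) +
                      (y[i] - y[j]) * (y[i] - y[j]);
          if (d2 <= e2) out.push_back(j); // includes i itself
        }
      }
  };

  std::vector<char> core(n, 0);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    neighbours(i, nb);
    core[i] = (int)nb.size() >= minpts;
  }

  int cl = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || lab[i] != 0) continue;
    ++cl;
    stack.assign(1, i);
    lab[i] = cl;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      if (!core[p]) continue;
      neighbours(p, nb);
      for (int q : nb) {
        if (lab[q] == 0) {
          lab[q] = cl;
          if (core[q]) stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Top-down distance-judgement segmentation of a normalized cloud.
// Points are processed in strictly descending normalized height (ties by
// index). The highest unassigned point seeds a tree unless it lies within t2
// of an existing apex; otherwise a point joins the tree owning its nearest
// already-assigned point if that 2D distance is <= t1.
// Returns labels 1..m (0 = unassigned/discarded).
// [[Rcpp::export]]
IntegerVector cpp_uls_segment(NumericVector x, NumericVector y,
                              NumericVector zn, double t1, double t2) {
  const int n = x.size();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return zn[a] > zn[b]; });

  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  double cs = t1;
  std::unordered_map<int64_t, std::vector<int>> assigned;
  auto keyof = [&](double px, double py) {
    return cell_key((int)std::floor((px - x0) / cs),
                    (int)std::floor((py - y0) / cs), 0);
  };

  std::vector<double> ax_, ay_; // apex positions per tree
  const double t1sq = t1 * t1, t2sq = t2 * t2;
  int ntree = 0;

  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    // nearest assigned point within t1 (assigned points live in cells of
    // size t1, so a 3x3 neighbourhood is sufficient)
    int ix = (int)std::floor((x[i] - x0) / cs);
    int iy = (int)std::floor((y[i] - y0) / cs);
    double bd = t1sq; int bl = 0;
    for (int cx = ix - 1; cx <= ix + 1; ++cx)
      for (int cy = iy - 1; cy <= iy + 1; ++cy) {
        auto it = assigned.find(cell_key(cx, cy, 0));
        if (it == assigned.end()) continue;
        for (int j : it->second) {
          double d2 = (x[i] - x[j]) * (x[i] - x[j]) +
                      (y[i] - y[j]) * (y[i] - y[j]);
          if (d2 <= bd) { bd = d2; bl = lab[j]; }
        }
      }
    if (bl > 0) {
      lab[i] = bl;
      assigned[keyof(x[i], y[i])].push_back(i);
      continue;
    }
    // candidate treetop: barred within t2 of an existing apex
    bool barred = false;
    for (int t = 0; t < ntree && !barred; ++t) {
      double d2 = (x[i] - ax_[t]) * (x[i] - ax_[t]) +
                  (y[i] - ay_[t]) * (y[i] - ay_[t]);
      if (d2 <= t2sq) barred = true;
    }
    if (!barred) {
      ++ntree;
      ax_.push_back(x[i]);
      ay_.push_back(y[i]);
      lab[i] = ntree;
      assigned[keyof(x[i], y[i])].push_back(i);
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation + progressive TIN densification
// ---------------------------------------------------------------------------

namespace {

struct Tri { int a, b, c; bool alive; };

inline double orient2d(double ax, double ay, double bx, double by, double cx,
                       double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// true if p lies inside the circumcircle of CCW triangle (a,b,c)
inline bool in_circle(double ax, double ay, double bx, double by, double cx,
                      double cy, double px, double py) {
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
               ad * (bdx * cdy - bdy * cdx);
  return det > 1e-12;
}

// Delaunay triangulation of (px, py); returns triangles as index triples.
std::vector<Tri> delaunay(const std::vector<double>& px,
                          const std::vector<double>& py) {
  const int n = (int)px.size();
  std::vector<double> x(px), y(py);
  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double d = std::max({xmax - xmin, ymax - ymin, 1.0}) * 100.0;
  double cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2;
  // super-triangle vertices appended at indices n, n+1, n+2
  x.push_back(cx - 2 * d); y.push_back(cy - d);
  x.push_back(cx + 2 * d); y.push_back(cy - d);
  x.push_back(cx);         y.push_back(cy + 2 * d);

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edge_count;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& tr = tris[t];
      if (in_circle(x[tr.a], y[tr.a], x[tr.b], y[tr.b], x[tr.c], y[tr.c],
                    x[i], y[i]))
        bad.push_back(t);
    }
    edge_count.clear();
    auto add_edge = [&](int u, int v) {
      auto e = std::minmax(u, v);
      edge_count[{e.first, e.second}]++;
    };
    for (int t : bad) {
      add_edge(tris[t].a, tris[t].b);
      add_edge(tris[t].b, tris[t].c);
      add_edge(tris[t].c, tris[t].a);
      tris[t].alive = false;
    }
    for (auto& kv : edge_count) {
      if (kv.second != 1) continue; // interior edge of the cavity
      int u = kv.first.first, v = kv.first.second;
      Tri nt{u, v, i, true};
      if (orient2d(x[u], y[u], x[v], y[v], x[i], y[i]) < 0)
        std::swap(nt.a, nt.b); // enforce CCW
      tris.push_back(nt);
    }
    // periodic compaction to keep the scan linear-ish
    if (tris.size() > 4000 && i % 512 == 0) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (auto& t : tris) if (t.alive) keep.push_back(t);
      tris.swap(keep);
    }
  }
  std::vector<Tri> out;
  for (auto& t : tris)
    if (t.alive && t.a < n && t.b < n && t.c < n) out.push_back(t);
  return out;
}

} // namespace

// Delaunay triangulation exposed for tests: returns an m x 3 matrix of
// 1-based vertex indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  auto tris = delaunay(px, py);
  IntegerMatrix out((int)tris.size(), 3);
  for (int i = 0; i < (int)tris.size(); ++i) {
    out(i, 0) = tris[i].a + 1;
    out(i, 1) = tris[i].b + 1;
    out(i, 2) = tris[i].c + 1;
  }
  return out;
}

// Progressive TIN densification ground filter.
//   seeds: 1-based indices of the seed ground points.
// Each round triangulates the current ground set (thinned to the lowest
// point per tin_cell x tin_cell block, which keeps the TIN non-degenerate
// on stem-dominated clouds), then accepts every unlabelled point whose
// perpendicular distance to its facet plane is <= max_dist and whose
// maximum angle to the facet vertices is <= max_angle (degrees); points
// within tight_tol of the facet are accepted on distance alone (the angle
// criterion is meaningless immediately above a vertex). Points outside the
// triangulation are tested against the facet with the nearest centroid.
// Returns a logical ground mask.
// [[Rcpp::export]]
LogicalVector cpp_iptd(NumericVector x, NumericVector y, NumericVector z,
                       IntegerVector seeds, double max_angle, double max_dist,
                       int max_iter, double tin_cell, double tight_tol) {
  const int n = x.size();
  LogicalVector ground(n, false);
  for (int i = 0; i < seeds.size(); ++i) ground[seeds[i] - 1] = true;
  const double tan_max = std::tan(max_angle * M_PI / 180.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // thin the current ground set: lowest point per tin_cell block
    std::unordered_map<int64_t, int> low;
    double bx = *std::min_element(x.begin(), x.end());
    double by = *std::min_element(y.begin(), y.end());
    for (int i = 0; i < n; ++i) {
      if (!ground[i]) continue;
      int64_t k = cell_key((int)std::floor((x[i] - bx) / tin_cell),
                           (int)std::floor((y[i] - by) / tin_cell), 0);
      auto it = low.find(k);
      if (it == low.end() || z[i] < z[it->second]) low[k] = i;
    }
    std::vector<int> gidx;
    gidx.reserve(low.size());
    for (auto& kv : low) gidx.push_back(kv.second);
    std::sort(gidx.begin(), gidx.end());
    if ((int)gidx.size() < 3) break;
    std::vector<double> gx(gidx.size()), gy(gidx.size());
    for (size_t i = 0; i < gidx.size(); ++i) {
      gx[i] = x[gidx[i]];
      gy[i] = y[gidx[i]];
    }
    auto tris = delaunay(gx, gy);
    if (tris.empty()) break; // degenerate; caller falls back

    // bbox grid over triangles for point location
    double xmin = *std::min_element(gx.begin(), gx.end());
    double xmax = *std::max_element(gx.begin(), gx.end());
    double ymin = *std::min_element(gy.begin(), gy.end());
    double ymax = *std::max_element(gy.begin(), gy.end());
    int nc = std::max(1, (int)std::sqrt((double)tris.size()));
    double csx = std::max((xmax - xmin) / nc, 1e-6);
    double csy = std::max((ymax - ymin) / nc, 1e-6);
    std::vector<std::vector<int>> tgrid(nc * nc);
    auto cell_of = [&](double px, double py) {
      int ix = std::min(nc - 1, std::max(0, (int)((px - xmin) / csx)));
      int iy = std::min(nc - 1, std::max(0, (int)((py - ymin) / csy)));
      return iy * nc + ix;
    };
    for (int t = 0; t < (int)tris.size(); ++t) {
      double txmin = std::min({gx[tris[t].a], gx[tris[t].b], gx[tris[t].c]});
      double txmax = std::max({gx[tris[t].a], gx[tris[t].b], gx[tris[t].c]});
      double tymin = std::min({gy[tris[t].a], gy[tris[t].b], gy[tris[t].c]});
      double tymax = std::max({gy[tris[t].a], gy[tris[t].b], gy[tris[t].c]});
      int ix0 = std::min(nc - 1, std::max(0, (int)((txmin - xmin) / csx)));
      int ix1 = std::min(nc - 1, std::max(0, (int)((txmax - xmin) / csx)));
      int iy0 = std::min(nc - 1, std::max(0, (int)((tymin - ymin) / csy)));
      int iy1 = std::min(nc - 1, std::max(0, (int)((tymax - ymin) / csy)));
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix)
          tgrid[iy * nc + ix].push_back(t);
    }
    // centroids for the outside-hull fallback
    std::vector<double> ctx(tris.size()), cty(tris.size());
    for (size_t t = 0; t < tris.size(); ++t) {
      ctx[t] = (gx[tris[t].a] + gx[tris[t].b] + gx[tris[t].c]) / 3.0;
      cty[t] = (gy[tris[t].a] + gy[tris[t].b] + gy[tris[t].c]) / 3.0;
    }

    auto test_against = [&](int i, int t) -> bool {
      int a = gidx[tris[t].a], b = gidx[tris[t].b], c = gidx[tris[t].c];
      double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
      double vx = x[c] - x[a], vy = y[c] - y[a], vz = z[c] - z[a];
      double nx = uy * vz - uz * vy;
      double ny = uz * vx - ux * vz;
      double nz = ux * vy - uy * vx;
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nn < 1e-12) return false;
      // sliver/steep facets have untrustworthy planes; never densify from
      // a facet steeper than ~78 degrees
      if (std::abs(nz) / nn < 0.2) return false;
      double dperp = std::abs(nx * (x[i] - x[a]) + ny * (y[i] - y[a]) +
                              nz * (z[i] - z[a])) / nn;
      if (dperp > max_dist) return false;
      if (dperp <= tight_tol) return true;
      for (int v : {a, b, c}) {
        double L = std::sqrt((x[i] - x[v]) * (x[i] - x[v]) +
                             (y[i] - y[v]) * (y[i] - y[v]) +
                             (z[i] - z[v]) * (z[i] - z[v]));
        double horiz = std::sqrt(std::max(L * L - dperp * dperp, 1e-12));
        if (dperp / horiz > tan_max) return false;
      }
      return true;
    };

    // locate the facet for point i; with exclude >= 0 (a local vertex
    // index), facets incident to that vertex are skipped, giving a
    // leave-one-out test for TIN vertices
    auto locate = [&](int i, int exclude) -> int {
      for (int t : tgrid[cell_of(x[i], y[i])]) {
        if (exclude >= 0 && (tris[t].a == exclude || tris[t].b == exclude ||
                             tris[t].c == exclude))
          continue;
        double d1 = orient2d(gx[tris[t].a], gy[tris[t].a], gx[tris[t].b],
                             gy[tris[t].b], x[i], y[i]);
        double d2 = orient2d(gx[tris[t].b], gy[tris[t].b], gx[tris[t].c],
                             gy[tris[t].c], x[i], y[i]);
        double d3 = orient2d(gx[tris[t].c], gy[tris[t].c], gx[tris[t].a],
                             gy[tris[t].a], x[i], y[i]);
        if (d1 >= -1e-9 && d2 >= -1e-9 && d3 >= -1e-9) return t;
      }
      // outside the hull (or excluded): nearest facet centroid
      int found = -1;
      double best = 1e300;
      for (size_t t = 0; t < tris.size(); ++t) {
        if (exclude >= 0 && (tris[t].a == exclude || tris[t].b == exclude ||
                             tris[t].c == exclude))
          continue;
        double d2c = (x[i] - ctx[t]) * (x[i] - ctx[t]) +
                     (y[i] - cty[t]) * (y[i] - cty[t]);
        if (d2c < best) { best = d2c; found = (int)t; }
      }
      return found;
    };

    int added = 0;
    for (int i = 0; i < n; ++i) {
      if (ground[i]) continue;
      int found = locate(i, -1);
      if (found >= 0 && test_against(i, found)) {
        ground[i] = true;
        ++added;
      }
    }
    if (added == 0 || iter == max_iter - 1) {
      // verification pass: points accepted against the sparse early TIN
      // must also pass against the final dense TIN (demotes stem bases and
      // low clutter admitted in the first rounds); TIN vertices are tested
      // leave-one-out against their non-incident neighbour facets
      std::vector<int> vert_of(n, -1);
      for (int v = 0; v < (int)gidx.size(); ++v) vert_of[gidx[v]] = v;
      for (int i = 0; i < n; ++i) {
        if (!ground[i]) continue;
        int found = locate(i, vert_of[i]);
        if (!(found >= 0 && test_against(i, found))) ground[i] = false;
      }
      break;
    }
  }
  return ground;
}
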