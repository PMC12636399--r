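// Clipped planar Voronoi tessellation by incremental half-plane clipping.
//
// Each generator's cell starts as the ROI rectangle and is clipped by the
// perpendicular bisector against nearby generators, visited in order of
// increasing distance via a uniform grid.  A generator j can only cut the
// cell of i when d(i,j)/2 is smaller than the current farthest cell vertex,
// which gives an exact early-stop criterion, so the whole diagram is
// O(n) expected for roughly uniform point sets.  Every cell is bounded by
// construction (clipped to the rectangle), cell areas tile the ROI exactly
// up to floating-point error, and the surviving bisector edges give the
// cell adjacency graph (shared Voronoi edge).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cand {
  double d2;
  int idx;
  bool operator>(const Cand& o) const { return d2 > o.d2; }
};

// Convex polygon with per-edge generator bookkeeping.  gen[k] is the index
// (0-based) of the generator whose bisector created the edge leaving vertex
// k, or -1 for an ROI wall edge.
struct Cell {
  std::vector<double> px, py;
  std::vector<int> gen;
};

// Clip `cell` by the half-plane of points closer to (cx,cy) than to (qx,qy).
// Keeps the side where (p - m) . d <= 0 with m the midpoint and d = q - c.
// Returns true when the polygon changed (the bisector cuts the cell).
bool clip_halfplane(Cell& cell, double cx, double cy, double qx, double qy,
                    int jgen, double eps) {
  const double mx = 0.5 * (cx + qx), my = 0.5 * (cy + qy);
  const double dx = qx - cx, dy = qy - cy;
  const size_t n = cell.px.size();
  if (n < 3) return false;

  std::vector<double> s(n);
  bool any_out = false, all_out = true;
  for (size_t k = 0; k < n; ++k) {
    s[k] = (cell.px[k] - mx) * dx + (cell.py[k] - my) * dy;
    if (s[k] > eps) any_out = true; else all_out = false;
  }
  if (!any_out) return false;
  if (all_out) { cell.px.clear(); cell.py.clear(); cell.gen.clear(); return true; }

  Cell out;
  out.px.reserve(n + 2); out.py.reserve(n + 2); out.gen.reserve(n + 2);
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1 == n) ? 0 : k + 1;
    bool in1 = s[k] <= eps, in2 = s[k2] <= eps;
    if (in1) {
      out.px.push_back(cell.px[k]);
      out.py.push_back(cell.py[k]);
      out.gen.push_back(cell.gen[k]);
    }
    if (in1 != in2) {
      double t = s[k] / (s[k] - s[k2]);
      out.px.push_back(cell.px[k] + t * (cell.px[k2] - cell.px[k]));
      out.py.push_back(cell.py[k] + t * (cell.py[k2] - cell.py[k]));
      // leaving the kept side: the polygon continues along the bisector
      // until it re-enters, so the edge leaving this vertex belongs to j;
      // re-entering: the rest of the original edge k is kept.
      out.gen.push_back(in1 ? jgen : cell.gen[k]);
    }
  }
  cell = out;
  return true;
}

double shoelace(const Cell& c) {
  const size_t n = c.px.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1 == n) ? 0 : k + 1;
    a += c.px[k] * c.py[k2] - c.px[k2] * c.py[k];
  }
  return 0.5 * std::fabs(a);
}

}  // namespace

// [[Rcpp::export(name = ".voronoi_clipped_cpp")]]
List voronoi_clipped_cpp(NumericVector x, NumericVector y,
                         double xmin, double xmax,
                         double ymin, double ymax) {
  const int n = x.size();
  const double w = xmax - xmin, h = ymax - ymin;
  const double eps = 1e-9 * std::max(w, h);

  // uniform bucket grid, ~1 point per bucket for uniform input
  int ng = std::max(1, (int)std::floor(std::sqrt((double)n)));
  const double gx = w / ng, gy = h / ng;
  std::vector<std::vector<int> > grid((size_t)ng * ng);
  std::vector<int> cellcol(n), cellrow(n);
  for (int i = 0; i < n; ++i) {
    int cc = std::min(ng - 1, std::max(0, (int)((x[i] - xmin) / gx)));
    int cr = std::min(ng - 1, (int)std::max(0, (int)((y[i] - ymin) / gy)));
    cellcol[i] = cc; cellrow[i] = cr;
    grid[(size_t)cr * ng + cc].push_back(i);
  }
  const double gmin = std::min(gx, gy);

  NumericVector area(n);
  List nbrs(n);
  LogicalVector boundary(n);

  for (int i = 0; i < n; ++i) {
    Cell cell;
    cell.px.assign(4, 0.0); cell.py.assign(4, 0.0); cell.gen.assign(4, -1);
    cell.px[0] = xmin; cell.py[0] = ymin;
    cell.px[1] = xmax; cell.py[1] = ymin;
    cell.px[2] = xmax; cell.py[2] = ymax;
    cell.px[3] = xmin; cell.py[3] = ymax;

    const double cx = x[i], cy = y[i];
    // farthest-vertex radius squared of the current cell
    double R2 = 0.0;
    for (int k = 0; k < 4; ++k) {
      double d2 = (cell.px[k] - cx) * (cell.px[k] - cx) +
                  (cell.py[k] - cy) * (cell.py[k] - cy);
      if (d2 > R2) R2 = d2;
    }

    std::priority_queue<Cand, std::vector<Cand>, std::greater<Cand> > heap;
    int ring = 0;
    bool rings_left = true;
    while (true) {
      // lazily pull in grid rings: a ring at Chebyshev index r is at least
      // (r-1)*gmin away, so gather only while the next ring could hold a
      // point nearer than the heap top and near enough to cut the cell
      while (rings_left) {
        double ring_min = (ring <= 1) ? 0.0 : (ring - 1) * gmin;
        double rm2 = ring_min * ring_min;
        if (rm2 > 4.0 * R2 || (!heap.empty() && rm2 > heap.top().d2)) break;
        int r0 = cellrow[i] - ring, r1 = cellrow[i] + ring;
        int c0 = cellcol[i] - ring, c1 = cellcol[i] + ring;
        for (int rr = r0; rr <= r1; ++rr) {
          if (rr < 0 || rr >= ng) continue;
          for (int cc = c0; cc <= c1; ++cc) {
            if (cc < 0 || cc >= ng) continue;
            if (ring > 0 && rr != r0 && rr != r1 && cc != c0 && cc != c1) continue;
            const std::vector<int>& b = grid[(size_t)rr * ng + cc];
            for (size_t t = 0; t < b.size(); ++t) {
              int j = b[t];
              if (j == i) continue;
              double d2 = (x[j] - cx) * (x[j] - cx) + (y[j] - cy) * (y[j] - cy);
              Cand cd; cd.d2 = d2; cd.idx = j;
              heap.push(cd);
            }
          }
        }
        ++ring;
        if (ring > ng + std::max(std::max(cellrow[i], ng - 1 - cellrow[i]),
                                 std::max(cellcol[i], ng - 1 - cellcol[i])))
          rings_left = false;  // every grid cell has been visited
      }
      if (heap.empty()) break;
      Cand top = heap.top();
      if (top.d2 > 4.0 * R2) break;  // bisector cannot reach the cell
      heap.pop();
      if (clip_halfplane(cell, cx, cy, x[top.idx], y[top.idx], top.idx, eps)) {
        if (cell.px.size() < 3) break;  // degenerate (coincident generators)
        R2 = 0.0;
        for (size_t k = 0; k < cell.px.size(); ++k) {
          double d2 = (cell.px[k] - cx) * (cell.px[k] - cx) +
                      (cell.py[k] - cy) * (cell.py[k] - cy);
          if (d2 > R2) R2 = d2;
        }
      }
    }

    area[i] = shoelace(cell);
    bool on_wall = false;
    std::vector<int> nb;
    for (size_t k = 0; k < cell.gen.size(); ++k) {
      size_t k2 = (k + 1 == cell.gen.size()) ? 0 : k + 1;
      double len2 = (cell.px[k2] - cell.px[k]) * (cell.px[k2] - cell.px[k]) +
                    (cell.py[k2] - cell.py[k]) * (cell.py[k2] - cell.py[k]);
      if (len2 <= eps * eps) continue;  // zero-length sliver edge
      if (cell.gen[k] < 0) on_wall = true;
      else nb.push_back(cell.gen[k] + 1);  // 1-based for R
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    nbrs[i] = IntegerVector(nb.begin(), nb.end());
    boundary[i] = on_wall;
  }

  return List::create(_["area"] = area, _["neighbors"] = nbrs,
                      _["on_boundary"] = boundary);
}
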