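#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <functional>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling of a binary image by breadth-first flood
// fill. Input: integer/logical matrix (non-zero = foreground). Output:
// integer matrix with labels 1..n, background 0.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(c0 * nr + r0);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(cc * nr + rr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

namespace {
struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::unordered_map<long long, std::vector<int> > cells;
  long long key(int ix, int iy) const {
    return (long long)ix * 2000003LL + iy;
  }
  Grid(const NumericVector &x, const NumericVector &y, double cellsize) {
    cell = cellsize;
    x0 = Rcpp::min(x); y0 = Rcpp::min(y);
    for (int i = 0; i < x.size(); ++i) {
      int ix = (int)std::floor((x[i] - x0) / cell);
      int iy = (int)std::floor((y[i] - y0) / cell);
      cells[key(ix, iy)].push_back(i);
    }
  }
};
}

// All unordered point pairs (i < j, 1-based) with Euclidean distance <= r.
// Bucket grid with cell size r; each pair reported once.
// [[Rcpp::export(name = ".radius_pairs")]]
IntegerMatrix radius_pairs(const NumericVector &x, const NumericVector &y,
                           double r) {
  const int n = x.size();
  if (n < 2 || r <= 0) return IntegerMatrix(0, 2);
  Grid g(x, y, r);
  const double r2 = r * r;
  std::vector<int> ai, aj;
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((x[i] - g.x0) / g.cell);
    int iy = (int)std::floor((y[i] - g.y0) / g.cell);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = g.cells.find(g.key(ix + dx, iy + dy));
        if (it == g.cells.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) { ai.push_back(i + 1); aj.push_back(j + 1); }
        }
      }
    }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// Exact nearest-neighbour distance for every point (expanding ring search on
// a bucket grid; falls back to full scan for tiny n).
// [[Rcpp::export(name = ".nn_dist")]]
NumericVector nn_dist(const NumericVector &x, const NumericVector &y) {
  const int n = x.size();
  NumericVector out(n);
  if (n < 2) stop("need at least 2 points");
  // initial cell size from a rough density guess
  double xr = Rcpp::max(x) - Rcpp::min(x), yr = Rcpp::max(y) - Rcpp::min(y);
  double area = std::max(xr * yr, 1e-9);
  double cell = std::max(std::sqrt(area / n), 1e-6);
  Grid g(x, y, cell);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((x[i] - g.x0) / g.cell);
    int iy = (int)std::floor((y[i] - g.y0) / g.cell);
    double best = R_PosInf;
    for (int ring = 0; ; ++ring) {
      for (int dx = -ring; dx <= ring; ++dx) {
        for (int dy = -ring; dy <= ring; ++dy) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          auto it = g.cells.find(g.key(ix + dx, iy + dy));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) best = d2;
          }
        }
      }
      // any point in an unscanned ring lies at distance >= ring * cell
      if (best < R_PosInf && std::sqrt(best) <= ring * g.cell) break;
      if (ring * g.cell > std::sqrt(xr * xr + yr * yr) + g.cell) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Union-find over edge list; returns 1-based component id per node.
// [[Rcpp::export(name = ".uf_components")]]
IntegerVector uf_components(int n, const IntegerMatrix &edges) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int k = 0; k < edges.nrow(); ++k) {
    int a = find(edges(k, 0) - 1), b = find(edges(k, 1) - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector comp(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; comp[i] = next; }
    else comp[i] = it->second;
  }
  return comp;
}
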