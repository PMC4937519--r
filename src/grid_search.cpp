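// Single-source shortest paths over the free (unoccupied) voxels of a
// regular grid. Moves connect 26-neighbours (or 6 when diag = false) with
// Euclidean step costs (1, sqrt 2, sqrt 3 voxels). Sources may be seeded with
// non-zero initial costs, which lets the caller fold the Calpha-to-surface
// Euclidean connection into the search. Optionally terminates early once all
// voxels in `stop_targets` have been finalized.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".grid_search_cpp")]]
List grid_search_cpp(LogicalVector occ, IntegerVector dims,
                     IntegerVector seeds, NumericVector seed_costs,
                     double voxel_size, bool diag,
                     IntegerVector stop_targets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occupancy length does not match dims");

  // neighbour offsets and step costs
  std::vector<int> dx, dy, dz;
  std::vector<double> w;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (!diag && m > 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
        w.push_back(std::sqrt((double)m) * voxel_size);
      }
  const int ndir = (int)dx.size();

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<int> pred(n, -1);   // 0-based predecessor, -1 = none/seed
  std::vector<char> done(n, 0);

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (R_xlen_t i = 0; i < seeds.size(); ++i) {
    int s = seeds[i] - 1;  // to 0-based
    if (s < 0 || s >= n) stop("seed voxel out of range");
    if (occ[s]) stop("seed voxel is occupied");
    double c = seed_costs[i];
    if (c < dist[s]) {
      dist[s] = c;
      pq.push(QE(c, s));
    }
  }

  // early-stop bookkeeping
  std::vector<char> is_target(stop_targets.size() ? n : 0, 0);
  R_xlen_t remaining = 0;
  for (R_xlen_t i = 0; i < stop_targets.size(); ++i) {
    int t = stop_targets[i] - 1;
    if (t < 0 || t >= n) stop("stop target out of range");
    if (!is_target[t]) { is_target[t] = 1; ++remaining; }
  }

  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (remaining > 0 && is_target[u]) {
      if (--remaining == 0) break;
    }
    int ux = u % nx, uy = (u / nx) % ny, uz = (int)(u / nxy);
    double du = dist[u];
    for (int k = 0; k < ndir; ++k) {
      int vx = ux + dx[k], vy = uy + dy[k], vz = uz + dz[k];
      if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz)
        continue;
      R_xlen_t v = vx + (R_xlen_t)nx * vy + nxy * vz;
      if (occ[v] || done[v]) continue;
      double alt = du + w[k];
      if (alt < dist[v]) {
        dist[v] = alt;
        pred[v] = u;
        pq.push(QE(alt, (int)v));
      }
    }
  }

  NumericVector out_dist(n);
  IntegerVector out_pred(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out_dist[i] = dist[i];
    out_pred[i] = pred[i] < 0 ? NA_INTEGER : pred[i] + 1;  // back to 1-based
  }
  return List::create(_["dist"] = out_dist, _["pred"] = out_pred);
}
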