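#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Truncated Dijkstra accumulation over an 8-connected raster.
// cost holds per-pixel crossing costs for a full orthogonal crossing; the
// edge weight between neighbouring cells u, v is
//   step_length / cell_size * (cost_u + cost_v) / 2,
// i.e. (cost_u + cost_v)/2 orthogonally and sqrt(2) times that diagonally
// (the cell size cancels). The focal cell starts at 0 regardless of its own
// cost. Cells whose accumulated cost would exceed the budget are never
// settled and stay +Inf, so the returned matrix is exact for all cells with
// accumulated cost <= budget.
// [[Rcpp::export]]
NumericMatrix dijkstra_accumulate(NumericMatrix cost, int focal_row,
                                  int focal_col, double budget) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const int fr = focal_row - 1, fc = focal_col - 1;
  if (fr < 0 || fr >= nr || fc < 0 || fc >= nc)
    stop("domain error: focal cell outside the grid");
  if (budget <= 0) stop("domain error: budget must be positive");

  NumericMatrix acc(nr, nc);
  std::fill(acc.begin(), acc.end(), R_PosInf);
  std::vector<bool> done(static_cast<size_t>(nr) * nc, false);

  typedef std::pair<double, int> Node;  // (dist, row + col*nr)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  const double SQRT2 = std::sqrt(2.0);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  acc(fr, fc) = 0.0;
  pq.push(Node(0.0, fr + fc * nr));

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    const int idx = top.second;
    if (done[idx]) continue;
    done[idx] = true;
    const int r = idx % nr, c = idx / nr;
    const double d = top.first;
    const double cu = cost(r, c);
    for (int k = 0; k < 8; ++k) {
      const int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      const int idx2 = r2 + c2 * nr;
      if (done[idx2]) continue;
      const bool diag = (dr[k] != 0 && dc[k] != 0);
      double w = 0.5 * (cu + cost(r2, c2));
      if (diag) w *= SQRT2;
      const double nd = d + w;
      if (nd > budget) continue;  // truncation: closed at exactly the budget
      if (nd < acc(r2, c2)) {
        acc(r2, c2) = nd;
        pq.push(Node(nd, idx2));
      }
    }
  }
  return acc;
}

// Count road/building cells inside circular windows around focal cells,
// with the denominator clipped at the landscape edge. Returns a matrix
// n_points x n_radii of percentages.
// [[Rcpp::export]]
NumericMatrix hmd_window_counts(IntegerMatrix layer, IntegerVector focal_rows,
                                IntegerVector focal_cols,
                                NumericVector radii_cells,
                                int road_code, int building_code) {
  const int nr = layer.nrow(), nc = layer.ncol();
  const int np = focal_rows.size(), ns = radii_cells.size();
  NumericMatrix out(np, ns);
  for (int s = 0; s < ns; ++s) {
    const double rad = radii_cells[s];
    const double rad2 = rad * rad;
    const int w = static_cast<int>(std::floor(rad));
    for (int p = 0; p < np; ++p) {
      const int fr = focal_rows[p] - 1, fc = focal_cols[p] - 1;
      long inwin = 0, hit = 0;
      for (int dr2 = -w; dr2 <= w; ++dr2) {
        const int r = fr + dr2;
        if (r < 0 || r >= nr) continue;
        for (int dc2 = -w; dc2 <= w; ++dc2) {
          const int c = fc + dc2;
          if (c < 0 || c >= nc) continue;
          if (static_cast<double>(dr2) * dr2 +
              static_cast<double>(dc2) * dc2 > rad2) continue;
          ++inwin;
          const int v = layer(r, c);
          if (v == road_code || v == building_code) ++hit;
        }
      }
      out(p, s) = inwin ? 100.0 * hit / inwin : 0.0;
    }
  }
  return out;
}
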