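// Multi-source Dijkstra on the 8-connected raster graph.
//
// Cells are graph nodes; masked cells take part in no edge. The cost of an
// edge between neighbouring cells a and b is the distance between their
// centers times a friction average:
//   mean_friction:    d * (f_a + f_b) / 2
//   mean_conductance: d / ((1/f_a + 1/f_b) / 2)
// Step distances are precomputed per row in R (on a geographic grid the
// horizontal and diagonal steps shrink with latitude; the vertical step is
// constant on the sphere).

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List dijkstra_grid(NumericMatrix friction, LogicalMatrix mask,
                   IntegerVector src_row, IntegerVector src_col,
                   IntegerVector src_label,
                   NumericVector hdist, NumericVector vdist,
                   NumericVector ddist, int averaging) {
  const int nr = friction.nrow(), nc = friction.ncol();
  const int n = nr * nc;
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<double> dist(n, inf);
  std::vector<int> label(n, NA_INTEGER);

  // (distance, label, node): label in the key makes tie-breaking by lowest
  // source index deterministic regardless of insertion order
  typedef std::tuple<double, int, int> QItem;
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem>> pq;

  for (int k = 0; k < src_row.size(); ++k) {
    int r = src_row[k] - 1, c = src_col[k] - 1;
    int id = r + c * nr;
    if (mask(r, c)) continue;  // caller decides whether this is an error
    if (dist[id] > 0.0 || src_label[k] < label[id]) {
      dist[id] = 0.0;
      label[id] = src_label[k];
      pq.push(QItem(0.0, src_label[k], id));
    }
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    double d0 = std::get<0>(pq.top());
    int lab = std::get<1>(pq.top());
    int u = std::get<2>(pq.top());
    pq.pop();
    if (d0 > dist[u] || (d0 == dist[u] && lab > label[u])) continue;
    int r = u % nr, c = u / nr;
    double fu = friction(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2)) continue;
      double fv = friction(r2, c2);
      double d;
      if (dr[k] == 0) d = hdist[r];
      else if (dc[k] == 0) d = vdist[std::min(r, r2)];
      else d = ddist[std::min(r, r2)];
      double w = (averaging == 0)
        ? d * 0.5 * (fu + fv)
        : d * 2.0 * fu * fv / (fu + fv);
      int v = r2 + c2 * nr;
      double nd = d0 + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        label[v] = lab;
        pq.push(QItem(nd, lab, v));
      } else if (nd == dist[v] && lab < label[v]) {
        label[v] = lab;
        pq.push(QItem(nd, lab, v));
      }
    }
  }

  NumericMatrix minutes(nr, nc);
  IntegerMatrix labels(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = r + c * nr;
      if (mask(r, c)) {
        minutes(r, c) = NA_REAL;
        labels(r, c) = NA_INTEGER;
      } else {
        minutes(r, c) = dist[id];
        labels(r, c) = std::isinf(dist[id]) ? NA_INTEGER : label[id];
      }
    }
  }
  return List::create(_["minutes"] = minutes, _["labels"] = labels);
}
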