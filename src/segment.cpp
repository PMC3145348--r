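#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Column-major throughout: idx = r + c * nr.

// Exact Euclidean dilation with nearest-object assignment.
// Each output pixel within `distance` of any object is assigned to the
// nearest object (squared integer distances, so ties are exact); ties go to
// the lower label because labels are visited in ascending order and only a
// strictly smaller distance replaces an assignment.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_labels(IntegerMatrix labels, double distance) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int nmax = 0;
  for (int i = 0; i < nr * nc; ++i) if (labels[i] > nmax) nmax = labels[i];
  IntegerMatrix out(nr, nc);
  if (nmax == 0) return out;
  const double d2max = distance * distance;
  std::vector< std::vector<int> > pr(nmax + 1), pc(nmax + 1);
  std::vector<int> rmin(nmax + 1, nr), rmax(nmax + 1, -1),
                   cmin(nmax + 1, nc), cmax(nmax + 1, -1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int k = labels(r, c);
      if (k > 0) {
        pr[k].push_back(r); pc[k].push_back(c);
        if (r < rmin[k]) rmin[k] = r;
        if (r > rmax[k]) rmax[k] = r;
        if (c < cmin[k]) cmin[k] = c;
        if (c > cmax[k]) cmax[k] = c;
      }
    }
  std::vector<long long> best(static_cast<size_t>(nr) * nc, -1);
  const int pad = static_cast<int>(std::ceil(distance));
  for (int k = 1; k <= nmax; ++k) {
    if (pr[k].empty()) continue;
    const int r0 = std::max(0, rmin[k] - pad), r1 = std::min(nr - 1, rmax[k] + pad);
    const int c0 = std::max(0, cmin[k] - pad), c1 = std::min(nc - 1, cmax[k] + pad);
    const size_t np = pr[k].size();
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        long long d2 = std::numeric_limits<long long>::max();
        for (size_t i = 0; i < np; ++i) {
          long long dr = r - pr[k][i], dc = c - pc[k][i];
          long long v = dr * dr + dc * dc;
          if (v < d2) { d2 = v; if (v == 0) break; }
        }
        if (static_cast<double>(d2) <= d2max) {
          size_t idx = static_cast<size_t>(r) + static_cast<size_t>(c) * nr;
          if (best[idx] < 0 || d2 < best[idx]) { best[idx] = d2; out[idx] = k; }
        }
      }
  }
  return out;
}

// Seeded geodesic propagation (Dijkstra). Foreground pixels are assigned to
// the seed reachable at minimal accumulated cost, a step from p to an
// 8-neighbour q costing sqrt(reg * len^2 + (I(q) - I(p))^2) with len the
// Euclidean step length. Equal-cost ties resolve to the lower seed label.
// Seed pixels keep their label regardless of the mask; unreachable
// foreground stays background.
// [[Rcpp::export]]
IntegerMatrix cpp_propagate(NumericMatrix img, IntegerMatrix seeds,
                            LogicalMatrix mask, double reg) {
  const int nr = img.nrow(), nc = img.ncol();
  const size_t n = static_cast<size_t>(nr) * nc;
  IntegerMatrix out(nr, nc);
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  typedef std::tuple<double, int, int> Node;  // cost, label, idx
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (size_t i = 0; i < n; ++i)
    if (seeds[i] > 0) { dist[i] = 0.0; out[i] = seeds[i]; pq.push(Node(0.0, seeds[i], (int)i)); }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double d = std::get<0>(nd); int lab = std::get<1>(nd), i = std::get<2>(nd);
    if (d > dist[i] || (d == dist[i] && lab > out[i])) continue;
    int r = i % nr, c = i / nr;
    for (int t = 0; t < 8; ++t) {
      int rr = r + dr[t], cc = c + dc[t];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t j = static_cast<size_t>(rr) + static_cast<size_t>(cc) * nr;
      if (!mask[j] && seeds[j] == 0) continue;
      double len = (t < 4) ? 1.0 : SQ2;
      double dI = img[j] - img[i];
      double w = std::sqrt(reg * len * len + dI * dI);
      double ndist = d + w;
      if (ndist < dist[j] || (ndist == dist[j] && lab < out[j])) {
        dist[j] = ndist; out[j] = lab;
        pq.push(Node(ndist, lab, (int)j));
      }
    }
  }
  return out;
}

// Marker-controlled watershed by priority flooding: pixels of the mask are
// claimed from the seeds outward in order of decreasing height (the distance
// transform), i.e. a flood of the negated height. 4-connected growth keeps
// the resulting objects 4-connected; insertion order breaks height ties
// deterministically.
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix height, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  const int nr = height.nrow(), nc = height.ncol();
  const size_t n = static_cast<size_t>(nr) * nc;
  IntegerMatrix out(nr, nc);
  typedef std::tuple<double, long long, int, int> Node; // -height, order, idx, label
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (size_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) { out[i] = seeds[i]; }
  for (size_t i = 0; i < n; ++i) {
    if (out[i] == 0) continue;
    int r = i % nr, c = i / nr;
    for (int t = 0; t < 4; ++t) {
      int rr = r + dr[t], cc = c + dc[t];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t j = static_cast<size_t>(rr) + static_cast<size_t>(cc) * nr;
      if (mask[j] && out[j] == 0)
        pq.push(Node(-height[j], counter++, (int)j, out[i]));
    }
  }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int i = std::get<2>(nd), lab = std::get<3>(nd);
    if (out[i] != 0) continue;
    out[i] = lab;
    int r = i % nr, c = i / nr;
    for (int t = 0; t < 4; ++t) {
      int rr = r + dr[t], cc = c + dc[t];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t j = static_cast<size_t>(rr) + static_cast<size_t>(cc) * nr;
      if (mask[j] && out[j] == 0)
        pq.push(Node(-height[j], counter++, (int)j, lab));
    }
  }
  return out;
}

// Connected-component labelling (4- or 8-connectivity), labels assigned in
// raster-scan (column-major) order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_cc(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const size_t n = static_cast<size_t>(nr) * nc;
  IntegerMatrix out(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int lab = 0;
  std::vector<int> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || out[i] != 0) continue;
    ++lab;
    stack.clear(); stack.push_back((int)i); out[i] = lab;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int r = p % nr, c = p / nr;
      for (int t = 0; t < nn; ++t) {
        int rr = r + dr8[t], cc = c + dc8[t];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        size_t j = static_cast<size_t>(rr) + static_cast<size_t>(cc) * nr;
        if (mask[j] && out[j] == 0) { out[j] = lab; stack.push_back((int)j); }
      }
    }
  }
  return out;
}
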