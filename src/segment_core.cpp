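#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for 4- or 8-connectivity, in a fixed scan order so that
// all labelling and flooding results are deterministic.
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dr, std::vector<int> &dc) {
  dr = {-1, 0, 0, 1};
  dc = {0, -1, 1, 0};
  if (connectivity == 8) {
    dr.insert(dr.end(), {-1, -1, 1, 1});
    dc.insert(dc.end(), {-1, 1, -1, 1});
  }
}

// Label connected foreground components of a logical mask.
// Labels are assigned in row-major scan order of each component's first pixel
// (column-major storage; scan follows R's matrix layout: down columns).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> dr, dc;
  neighbour_offsets(connectivity, dr, dc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

struct FloodNode {
  double elev;
  long long seq;
  int r, c, label;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.seq > b.seq;                          // FIFO among ties
  }
};

// Marker-based watershed by priority flooding of an elevation surface
// (typically the negated distance transform), restricted to the mask.
// Markers are seeded in increasing label order so that at equal elevation the
// lower label floods first, giving boundary pixels to the lower label id.
// [[Rcpp::export(name = ".marker_flood_cpp")]]
IntegerMatrix marker_flood_cpp(NumericMatrix elev, IntegerMatrix markers,
                               LogicalMatrix mask, int connectivity) {
  int nr = elev.nrow(), nc = elev.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation, markers and mask must share one shape");
  std::vector<int> dr, dc;
  neighbour_offsets(connectivity, dr, dc);
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long long seq = 0;

  // Collect marker seeds ordered by label id, then scan order.
  int maxlab = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > maxlab) maxlab = markers(r, c);
  for (int want = 1; want <= maxlab; ++want)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (markers(r, c) == want && mask(r, c))
          pq.push({elev(r, c), seq++, r, c, want});

  while (!pq.empty()) {
    FloodNode nd = pq.top(); pq.pop();
    if (lab(nd.r, nd.c) != 0) continue;
    lab(nd.r, nd.c) = nd.label;
    for (size_t k = 0; k < dr.size(); ++k) {
      int rr = nd.r + dr[k], cc = nd.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && lab(rr, cc) == 0)
        pq.push({elev(rr, cc), seq++, rr, cc, nd.label});
    }
  }
  return lab;
}
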