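// Connected-component labeling and Meyer-style marker-controlled watershed
// on 2D/3D grids. Volumes arrive as flat vectors in R's column-major layout
// with dim = (Z, Y, X); 2D images use Z = 1.

#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// neighbour offsets for the requested connectivity
// 2D: 4 or 8 (in-plane); 3D: 6 or 26
static std::vector<std::array<int, 3>> neighbours(int connectivity) {
  std::vector<std::array<int, 3>> out;
  if (connectivity == 4 || connectivity == 6) {
    out.push_back({1, 0, 0});
    out.push_back({-1, 0, 0});
    out.push_back({0, 1, 0});
    out.push_back({0, -1, 0});
    if (connectivity == 6) {
      out.push_back({0, 0, 1});
      out.push_back({0, 0, -1});
    }
  } else {
    int zr = (connectivity == 26) ? 1 : 0;
    for (int dz = -zr; dz <= zr; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          out.push_back({dz, dy, dx});
        }
  }
  // entries are (dz, dy, dx) for 3D; for 2D input (4/8) the first axis of
  // the stored offsets maps onto Y and the second onto X below
  return out;
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  if (connectivity == 4 || connectivity == 8) {
    // in-plane connectivity: build (0, dy, dx) offsets
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dy == 0 && dx == 0) continue;
        if (connectivity == 4 && dy != 0 && dx != 0) continue;
        offs.push_back({0, dy, dx});
      }
  } else {
    offs = neighbours(connectivity);
  }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    labels[i] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = v % nz, y = (v / nz) % ny, x = v / ((R_xlen_t)nz * ny);
      for (auto &o : offs) {
        int z2 = z + o[0], y2 = y + o[1], x2 = x + o[2];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)x2 * nz * ny + (R_xlen_t)y2 * nz + z2;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

struct QEntry {
  double priority;
  R_xlen_t order; // FIFO tie-break for equal priorities
  R_xlen_t idx;
  int label;
};

struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;
  }
};

// Meyer's flooding: seeds grow outward over the priority relief (typically a
// gradient magnitude), lowest priority first. markers: 0 = unknown, >0 = seed
// label. Returns the completed label image.
// [[Rcpp::export(name = ".marker_watershed_cpp")]]
IntegerVector marker_watershed_cpp(NumericVector priority, IntegerVector markers,
                                   IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(clone(markers));
  std::vector<std::array<int, 3>> offs;
  if (connectivity == 4 || connectivity == 8) {
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dy == 0 && dx == 0) continue;
        if (connectivity == 4 && dy != 0 && dx != 0) continue;
        offs.push_back({0, dy, dx});
      }
  } else {
    offs = neighbours(connectivity);
  }
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  R_xlen_t order = 0;
  std::vector<bool> queued(n, false);

  auto push_neighbours = [&](R_xlen_t v, int lab) {
    int z = v % nz, y = (v / nz) % ny, x = v / ((R_xlen_t)nz * ny);
    for (auto &o : offs) {
      int z2 = z + o[0], y2 = y + o[1], x2 = x + o[2];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t w = (R_xlen_t)x2 * nz * ny + (R_xlen_t)y2 * nz + z2;
      if (labels[w] == 0 && !queued[w]) {
        queued[w] = true;
        pq.push({priority[w], order++, w, lab});
      }
    }
  };

  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > 0) push_neighbours(i, labels[i]);

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    if (labels[e.idx] != 0) continue;
    labels[e.idx] = e.label;
    push_neighbours(e.idx, e.label);
  }
  return labels;
}
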