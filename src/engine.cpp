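#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Arrays arrive as R column-major vectors with dim (nz, ny, nx):
// linear index = z + nz*(y + ny*x), so linear order is the (z, then y,
// then x) scan order the labeling contract requires.

static void neighbour_offsets(int connectivity,
                              std::vector<int> &dz,
                              std::vector<int> &dy,
                              std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) ||
            (connectivity == 18 && m > 2)) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// Connected-component labeling of a 3D boolean mask. Components are
// labeled 1..K in decreasing size order; equal sizes break by the scan
// order of each component's first voxel.
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  const int nb = (int)dz.size();

  std::vector<int> prov(n, 0);        // provisional label, discovery order
  std::vector<R_xlen_t> sizes;        // indexed by provisional label - 1
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || prov[i] != 0) continue;
    ++next;
    prov[i] = next;
    R_xlen_t sz = 0;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++sz;
      int x = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v - (R_xlen_t)x * nz * ny);
      int y = rem / nz;
      int z = rem - y * nz;
      for (int k = 0; k < nb; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
            xx < 0 || xx >= nx) continue;
        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && prov[w] == 0) {
          prov[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(sz);
  }

  // rank provisional labels by decreasing size; stable sort keeps
  // discovery (scan) order among ties
  std::vector<int> order(next);
  for (int k = 0; k < next; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(),
                   [&sizes](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> rank(next);
  for (int r = 0; r < next; ++r) rank[order[r]] = r + 1;

  IntegerVector lab(n);
  lab.attr("dim") = dims;
  for (R_xlen_t i = 0; i < n; ++i)
    lab[i] = prov[i] ? rank[prov[i] - 1] : 0;
  IntegerVector out_sizes(next);
  for (int r = 0; r < next; ++r)
    out_sizes[r] = (int)sizes[order[r]];
  return List::create(_["labels"] = lab, _["sizes"] = out_sizes);
}

// One growth pass: every voxel with grey value >= cit that is connected
// through such voxels to a current segment is claimed by the first
// breadth-first wavefront to reach it; equidistant ties go to the
// smaller label. Existing labels are never reassigned; mask components
// touching no segment stay background.
// [[Rcpp::export]]
IntegerVector cpp_grow_once(IntegerVector labels, IntegerVector vol,
                            int cit, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  const int nb = (int)dz.size();

  IntegerVector out = clone(labels);
  out.attr("dim") = dims;
  std::vector<R_xlen_t> frontier, next_frontier;
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] > 0) frontier.push_back(i);

  std::vector<int> claim(n, 0);
  while (!frontier.empty()) {
    next_frontier.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      R_xlen_t v = frontier[f];
      int L = out[v];
      int x = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v - (R_xlen_t)x * nz * ny);
      int y = rem / nz;
      int z = rem - y * nz;
      for (int k = 0; k < nb; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
            xx < 0 || xx >= nx) continue;
        R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (out[w] != 0 || vol[w] < cit) continue;
        if (claim[w] == 0) {
          claim[w] = L;
          next_frontier.push_back(w);
        } else if (L < claim[w]) {
          claim[w] = L;        // simultaneous tie -> smaller label
        }
      }
    }
    for (size_t f = 0; f < next_frontier.size(); ++f) {
      R_xlen_t w = next_frontier[f];
      out[w] = claim[w];
      claim[w] = 0;
    }
    frontier.swap(next_frontier);
  }
  return out;
}

// One-voxel dilation of every segment by its 26-neighbourhood shell.
// A background voxel adjacent to shells of two or more distinct
// segments is contested and stays background; existing labels are
// never overwritten. An optional limit mask restricts which background
// voxels may be claimed.
// [[Rcpp::export]]
IntegerVector cpp_dilate_labels(IntegerVector labels, IntegerVector dims,
                                LogicalVector limit) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const bool has_limit = limit.size() == n;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(26, dz, dy, dx);
  const int nb = (int)dz.size();

  IntegerVector out = clone(labels);
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] != 0) continue;
    if (has_limit && !limit[i]) continue;
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int rem = (int)(i - (R_xlen_t)x * nz * ny);
    int y = rem / nz;
    int z = rem - y * nz;
    int found = 0;
    bool contested = false;
    for (int k = 0; k < nb; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
          xx < 0 || xx >= nx) continue;
      R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      int L = labels[w];
      if (L == 0) continue;
      if (found == 0) found = L;
      else if (L != found) { contested = true; break; }
    }
    if (found != 0 && !contested) out[i] = found;
  }
  return out;
}
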