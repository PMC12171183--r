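#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling, connectivity 6 (faces), 18 (+edges) or
// 26 (+corners). Input is a logical array in R column-major order.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector arr, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != arr.size()) stop("dim does not match array length");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector lab(arr.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < arr.size(); ++s) {
    if (!arr[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int idx = xx + nx * (yy + ny * zz);
        if (arr[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}

// Radius-limited region growing on one slice. Starting from the seed (0-based
// linear index), repeatedly admit any ROI pixel within Euclidean distance <= r
// (pixel units) of a region pixel whose |FF - ff_median| <= ff_median.
// single_pass restricts growth to one disk sweep around the seed.
// [[Rcpp::export(name = ".grow_region_cpp")]]
LogicalMatrix grow_region_cpp(NumericMatrix ff, LogicalMatrix roi,
                              double ff_median, int r, int seed_idx,
                              bool single_pass) {
  const int nx = ff.nrow(), ny = ff.ncol();
  if (roi.nrow() != nx || roi.ncol() != ny) stop("ff/roi shape mismatch");
  if (r < 1) stop("r must be >= 1");

  std::vector<int> dxs, dys;
  const int r2 = r * r;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      if (dx == 0 && dy == 0) continue;
      if (dx * dx + dy * dy <= r2) { dxs.push_back(dx); dys.push_back(dy); }
    }

  std::vector<char> eligible((size_t)nx * ny, 0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double v = ff(i, j);
      if (roi(i, j) && std::isfinite(v) && std::fabs(v - ff_median) <= ff_median)
        eligible[i + (size_t)nx * j] = 1;
    }

  LogicalMatrix region(nx, ny);
  std::queue<int> q;
  region[seed_idx] = true;
  q.push(seed_idx);
  bool first = true;
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int x = cur % nx, y = cur / nx;
    for (size_t k = 0; k < dxs.size(); ++k) {
      int xx = x + dxs[k], yy = y + dys[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
      int idx = xx + nx * yy;
      if (eligible[idx] && !region[idx]) {
        region[idx] = true;
        if (!single_pass) q.push(idx);
      }
    }
    if (single_pass && first) break;
    first = false;
  }
  return region;
}

// Cumulative ordered-pair counts #{(i,j): i != j, d_ij <= radii[k]} for an
// increasing radius grid; the Ripley K numerator.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
NumericVector pair_counts_cpp(NumericMatrix pts, NumericVector radii) {
  const int n = pts.nrow();
  const int nr = radii.size();
  std::vector<double> bins(nr + 1, 0.0);
  const double rmax = nr > 0 ? radii[nr - 1] : 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rmax) continue;
      int lo = 0, hi = nr - 1, pos = nr;
      while (lo <= hi) {  // first k with radii[k] >= d
        int mid = (lo + hi) / 2;
        if (radii[mid] >= d) { pos = mid; hi = mid - 1; } else lo = mid + 1;
      }
      bins[pos] += 2.0;
    }
  }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) { acc += bins[k]; out[k] = acc; }
  return out;
}
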