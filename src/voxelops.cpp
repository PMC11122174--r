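#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Linear index convention matches R arrays: idx = i + nx*(j + ny*k), 0-based here.

static inline bool in_grid(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
}

// Binary dilation (or erosion) with an explicit offset list (rows of di,dj,dk).
// Outside the grid counts as background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int no = offsets.nrow();
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        bool acc = dilate ? false : true;
        for (int o = 0; o < no; ++o) {
          const int ii = i + offsets(o, 0);
          const int jj = j + offsets(o, 1);
          const int kk = k + offsets(o, 2);
          bool v = in_grid(ii, jj, kk, nx, ny, nz) &&
                   mask[ii + nx * (jj + ny * kk)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[idx] = acc;
      }
    }
  }
  return out;
}

// Iterative 6-connected front propagation from seed voxels, restricted to
// `allowed`. One voxel layer per iteration. A leak guard compares the voxels
// added in an iteration (after `warmup` iterations) against the median of all
// previous per-iteration increments.
// [[Rcpp::export]]
List cpp_region_grow(LogicalVector allowed, IntegerVector dims,
                     IntegerVector seeds, int max_iter,
                     double leak_factor, int warmup,
                     double max_voxels = -1.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask(allowed.size());
  std::vector<int> frontier;
  for (int s = 0; s < seeds.size(); ++s) {
    int idx = seeds[s];
    if (idx < 0 || idx >= (int)allowed.size())
      stop("seed index out of bounds");
    if (!allowed[idx]) continue;
    if (!mask[idx]) { mask[idx] = true; frontier.push_back(idx); }
  }
  if (frontier.empty()) stop("no seed voxel lies in the growable region");
  std::vector<double> counts;
  bool leak = false, exhausted = false;
  double total = (double)frontier.size();
  int it = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!frontier.empty()) {
    if (it >= max_iter) { exhausted = true; break; }
    ++it;
    std::vector<int> next;
    for (size_t f = 0; f < frontier.size(); ++f) {
      const int idx = frontier[f];
      const int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
        const int nidx = ii + nx * (jj + ny * kk);
        if (allowed[nidx] && !mask[nidx]) {
          mask[nidx] = true;
          next.push_back(nidx);
        }
      }
    }
    const double added = (double)next.size();
    if (added == 0) break;
    total += added;
    if (max_voxels > 0 && total > max_voxels) { leak = true; break; }
    if (it > warmup && !counts.empty()) {
      std::vector<double> prev(counts);
      std::nth_element(prev.begin(), prev.begin() + prev.size() / 2, prev.end());
      double med = prev[prev.size() / 2];
      if (prev.size() % 2 == 0) {
        std::nth_element(prev.begin(), prev.begin() + prev.size() / 2 - 1,
                         prev.end());
        med = 0.5 * (med + prev[prev.size() / 2 - 1]);
      }
      if (med > 0 && added > leak_factor * med) { leak = true; break; }
    }
    counts.push_back(added);
    frontier.swap(next);
  }
  return List::create(_["mask"] = mask,
                      _["added"] = NumericVector(counts.begin(), counts.end()),
                      _["iterations"] = it,
                      _["leak"] = leak,
                      _["exhausted"] = exhausted);
}

// Connected component labels (6- or 26-connectivity) for a sparse voxel
// subset (0-based linear indices). Returns 1-based labels in input order.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector idx, IntegerVector dims,
                             int conn = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<int, int> pos;
  pos.reserve(idx.size() * 2);
  for (int s = 0; s < idx.size(); ++s) pos[idx[s]] = s;
  IntegerVector label(idx.size(), 0);
  int cur = 0;
  for (int s = 0; s < idx.size(); ++s) {
    if (label[s]) continue;
    ++cur;
    std::queue<int> q;
    q.push(s);
    label[s] = cur;
    while (!q.empty()) {
      const int t = q.front(); q.pop();
      const int lin = idx[t];
      const int i = lin % nx, j = (lin / nx) % ny, k = lin / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (conn == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) > 1)
              continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
            auto hit = pos.find(ii + nx * (jj + ny * kk));
            if (hit != pos.end() && !label[hit->second]) {
              label[hit->second] = cur;
              q.push(hit->second);
            }
          }
    }
  }
  return label;
}

// Separable Gaussian smoothing, sigma given per axis in voxel units,
// truncated at 3 sigma, kernel renormalized at the borders.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector a = clone(vol), b(vol.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    for (int t = -r; t <= r; ++t) w[t + r] = std::exp(-0.5 * t * t / (s * s));
    const int len = n[ax], st = stride[ax];
    const int nlines = (int)vol.size() / len;
    // iterate over all lines along axis ax
    for (int line = 0; line < nlines; ++line) {
      // decompose line number into the two non-axis coordinates
      int rem = line, base = 0;
      for (int other = 0; other < 3; ++other) {
        if (other == ax) continue;
        const int c = rem % n[other];
        rem /= n[other];
        base += c * stride[other];
      }
      for (int p = 0; p < len; ++p) {
        double acc = 0, norm = 0;
        const int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int q = lo; q <= hi; ++q) {
          const double wt = w[q - p + r];
          acc += wt * a[base + q * st];
          norm += wt;
        }
        b[base + p * st] = acc / norm;
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Marching tetrahedra over the voxel-center lattice. Each cube of 8
// neighboring voxel centers is split into 6 tetrahedra sharing the main
// diagonal; the iso-surface (field > iso inside) is emitted as triangles with
// vertices in physical mm (voxel center = origin + (index + 0.5) * spacing).
// Returns an n x 9 matrix of triangle vertex coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_marching_tets(NumericVector field, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  std::vector<double> tri;
  tri.reserve(1 << 16);
  double cx[8], cy[8], cz[8], cf[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + (c & 1), jj = j + ((c >> 1) & 1),
                    kk = k + ((c >> 2) & 1);
          const double f = field[ii + nx * (jj + ny * kk)];
          cf[c] = f;
          cx[c] = origin[0] + (ii + 0.5) * spacing[0];
          cy[c] = origin[1] + (jj + 0.5) * spacing[1];
          cz[c] = origin[2] + (kk + 0.5) * spacing[2];
          if (f > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int *v = tets[t];
          int above[4], below[4], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[v[c]] > iso) above[na++] = v[c];
            else below[nb++] = v[c];
          }
          if (na == 0 || na == 4) continue;
          auto edge = [&](int a, int b, double *p) {
            const double t0 = (iso - cf[a]) / (cf[b] - cf[a]);
            p[0] = cx[a] + t0 * (cx[b] - cx[a]);
            p[1] = cy[a] + t0 * (cy[b] - cy[a]);
            p[2] = cz[a] + t0 * (cz[b] - cz[a]);
          };
          double p[4][3];
          if (na == 1 || na == 3) {
            const int apex = (na == 1) ? above[0] : below[0];
            const int *rest = (na == 1) ? below : above;
            for (int c = 0; c < 3; ++c) edge(apex, rest[c], p[c]);
            for (int c = 0; c < 3; ++c)
              for (int d = 0; d < 3; ++d) tri.push_back(p[c][d]);
          } else { // na == 2: quad e(a0,b0) e(a0,b1) e(a1,b1) e(a1,b0)
            edge(above[0], below[0], p[0]);
            edge(above[0], below[1], p[1]);
            edge(above[1], below[1], p[2]);
            edge(above[1], below[0], p[3]);
            const int q1[3] = {0, 1, 2}, q2[3] = {0, 2, 3};
            for (int c = 0; c < 3; ++c)
              for (int d = 0; d < 3; ++d) tri.push_back(p[q1[c]][d]);
            for (int c = 0; c < 3; ++c)
              for (int d = 0; d < 3; ++d) tri.push_back(p[q2[c]][d]);
          }
        }
      }
    }
  }
  const int ntri = (int)tri.size() / 9;
  NumericMatrix out(ntri, 9);
  for (int r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tri[9 * r + c];
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing in mm; distance to the nearest TRUE voxel, measured
// between voxel centers. Returns +Inf where the mask is empty.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w2, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INFINITY) continue;  // no source in this cell
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
      continue;
    }
    double s;
    for (;;) {
      s = ((f[q] + w2 * (double)q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY; s = NAN; }
        else continue;
      }
      break;
    }
    if (std::isnan(s)) { z[1] = INFINITY; continue; }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  if (k < 0) {  // caller skips all-empty lines, but be safe
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqdist(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(mask.size());
  for (int i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? 0.0 : INFINITY;
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax], st = stride[ax];
    const double w2 = spacing[ax] * spacing[ax];
    const int nlines = (int)mask.size() / len;
    std::vector<double> f(len), d(len);
    for (int line = 0; line < nlines; ++line) {
      int rem = line, base = 0;
      for (int other = 0; other < 3; ++other) {
        if (other == ax) continue;
        const int c = rem % n[other];
        rem /= n[other];
        base += c * stride[other];
      }
      bool anyfinite = false;
      for (int p = 0; p < len; ++p) {
        f[p] = out[base + p * st];
        if (f[p] != INFINITY) anyfinite = true;
      }
      if (!anyfinite) continue;
      dt1d(f, d, w2, len);
      for (int p = 0; p < len; ++p) out[base + p * st] = d[p];
    }
  }
  return out;
}
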