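// Voxel-level kernels for 3D binary morphology and labeling.
//
// Index convention throughout: arrays are column-major with x fastest,
// then y, then z (the native R array layout); linear index
// i + nx*(j + ny*k). Scan order therefore runs z slowest, matching the
// deterministic component-ordering contract of the R level.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared-distance transform (lower envelope of parabolas).
// f: input squared distances (0 at sources, DT_INF elsewhere); d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in index space) from every voxel to the
// nearest source voxel. Voxels with src == TRUE are sources (distance 0).
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector src, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = src[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; k++) f[k] = out[base + nxy * k];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; k++) out[base + nxy * k] = d[k];
    }
  return out;
}

// Separable box (cube) erosion/dilation with out-of-bounds = background.
// [[Rcpp::export]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dim, int radius,
                            bool erode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; i++) cur[i] = mask[i] ? 1 : 0;

  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    int len = dims[ax];
    R_xlen_t st = strides[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = dims[o1], n2 = dims[o2];
    R_xlen_t st1 = strides[o1], st2 = strides[o2];
    for (int b = 0; b < n2; b++)
      for (int a = 0; a < n1; a++) {
        R_xlen_t base = (R_xlen_t)a * st1 + (R_xlen_t)b * st2;
        for (int i = 0; i < len; i++) {
          char val;
          if (erode) {
            // window must lie fully inside and be all-foreground
            if (i - radius < 0 || i + radius >= len) {
              val = 0;
            } else {
              val = 1;
              for (int w = i - radius; w <= i + radius; w++)
                if (!cur[base + st * w]) { val = 0; break; }
            }
          } else {
            val = 0;
            int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
            for (int w = lo; w <= hi; w++)
              if (cur[base + st * w]) { val = 1; break; }
          }
          nxt[base + st * i] = val;
        }
      }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = cur[i] != 0;
  return out;
}

// Iterative voting hole fill. Background voxels flip to foreground when at
// least half the box neighborhood (excluding the center; only in-bounds
// voxels counted, axes of extent 1 contribute no neighbors) plus `majority`
// neighbors are foreground. Foreground never flips. Returns the converged
// mask and the number of iterations actually applied.
// [[Rcpp::export]]
List cpp_voting_fill(LogicalVector mask, IntegerVector dim, int radius,
                     int max_iterations, int majority) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> cur(n), s1(n), s2(n), s3(n);
  for (R_xlen_t i = 0; i < n; i++) cur[i] = mask[i] ? 1 : 0;

  long nb = 1;
  if (nx > 1) nb *= 2 * radius + 1;
  if (ny > 1) nb *= 2 * radius + 1;
  if (nz > 1) nb *= 2 * radius + 1;
  long thr = (nb - 1) / 2 + majority;

  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int iters = 0;
  for (int it = 0; it < max_iterations; it++) {
    // running box sums along x, y, z (clipped at bounds => OOB counts 0)
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++) {
        R_xlen_t base = nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; i++) {
          int lo = std::max(0, i - radius), hi = std::min(nx - 1, i + radius);
          int s = 0;
          if (i == 0) {
            for (int w = lo; w <= hi; w++) s += cur[base + w];
          } else {
            s = s1[base + i - 1];
            if (i - radius - 1 >= 0) s -= cur[base + i - radius - 1];
            if (i + radius <= nx - 1) s += cur[base + i + radius];
          }
          s1[base + i] = s;
        }
      }
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + nxy * k;
        for (int j = 0; j < ny; j++) {
          int s;
          if (j == 0) {
            s = 0;
            int hi = std::min(ny - 1, radius);
            for (int w = 0; w <= hi; w++) s += s1[base + (R_xlen_t)nx * w];
          } else {
            s = s2[base + (R_xlen_t)nx * (j - 1)];
            if (j - radius - 1 >= 0) s -= s1[base + (R_xlen_t)nx * (j - radius - 1)];
            if (j + radius <= ny - 1) s += s1[base + (R_xlen_t)nx * (j + radius)];
          }
          s2[base + (R_xlen_t)nx * j] = s;
        }
      }
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; k++) {
          int s;
          if (k == 0) {
            s = 0;
            int hi = std::min(nz - 1, radius);
            for (int w = 0; w <= hi; w++) s += s2[base + nxy * w];
          } else {
            s = s3[base + nxy * (k - 1)];
            if (k - radius - 1 >= 0) s -= s2[base + nxy * (k - radius - 1)];
            if (k + radius <= nz - 1) s += s2[base + nxy * (k + radius)];
          }
          s3[base + nxy * k] = s;
        }
      }
    long flips = 0;
    for (R_xlen_t i = 0; i < n; i++) {
      if (!cur[i] && s3[i] >= thr) {  // center is background: sum == neighbor count
        cur[i] = 1;
        flips++;
      }
    }
    iters = it + 1;
    if (flips == 0) break;
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = cur[i] != 0;
  return List::create(_["mask"] = out, _["iterations"] = iters);
}

// Connected-component labeling (6- or 26-connectivity). Components are
// numbered 1..K in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; c++)
    for (int b = -1; b <= 1; b++)
      for (int a = -1; a <= 1; a++) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        dx.push_back(a);
        dy.push_back(b);
        dz.push_back(c);
      }
  size_t nn = dx.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / nxy);
      for (size_t q = 0; q < nn; q++) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t t = ii + (R_xlen_t)nx * jj + nxy * kk;
        if (mask[t] && !lab[t]) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}

// Union-find over an edge list; membership labeled 1..K by first occurrence.
// [[Rcpp::export]]
IntegerVector cpp_graph_components(IntegerMatrix edges, int nv) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  for (int e = 0; e < edges.nrow(); e++) {
    int a = find(edges(e, 0) - 1), b = find(edges(e, 1) - 1);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  IntegerVector out(nv);
  std::vector<int> relabel(nv, 0);
  int next = 0;
  for (int i = 0; i < nv; i++) {
    int r = find(i);
    if (!relabel[r]) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  return out;
}
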