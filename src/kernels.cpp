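#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over the three axes. Distances are in voxel units on an isotropic
// grid; callers multiply by spacing^2 for millimetres.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  // lower envelope over the finite parabolas only; +Inf entries (no source
  // anywhere along this line yet) cannot contribute
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite entry
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sedt(IntegerVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? 0.0 : INF;

  std::vector<double> f, g;
  // pass along x
  f.resize(nx); g.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = d[base + i]; if (std::isfinite(f[i])) any = true; }
      if (!any) continue;
      dt1d(f, g, nx);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[base + (R_xlen_t)nx * j]; if (std::isfinite(f[j])) any = true; }
      if (!any) continue;
      dt1d(f, g, ny);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = g[j];
    }
  // pass along z
  f.resize(nz); g.resize(nz);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[base + sz * k]; if (std::isfinite(f[k])) any = true; }
      if (!any) continue;
      dt1d(f, g, nz);
      for (int k = 0; k < nz; ++k) d[base + sz * k] = g[k];
    }
  return d;
}

// ---------------------------------------------------------------------------
// GLCM accumulation: symmetric co-occurrence counts over the 13 unique 3D
// directions at Chebyshev distance 1. Input is the set of in-region voxels
// (0-based linear indices) with gray levels 1..G; returns a G x G x 13 count
// array. Voxels outside the region never co-occur.
// ---------------------------------------------------------------------------

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// scratch buffer reused across calls to avoid reallocating a full-volume
// level map for every band/filter combination
static std::vector<int> g_levmap;

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector idx, IntegerVector lev, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t m = idx.size();
  if ((R_xlen_t)g_levmap.size() < nvox) g_levmap.assign((size_t)nvox, 0);
  std::vector<int>& levmap = g_levmap;
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = lev[t];

  NumericVector out((R_xlen_t)G * G * 13);
  const R_xlen_t GG = (R_xlen_t)G * G;
  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t p = idx[t];
    int i = (int)(p % nx);
    int rest = (int)(p / nx);
    int j = rest % ny;
    int k = rest / ny;
    int li = lev[t];
    for (int d = 0; d < 13; ++d) {
      int ii = i + DIR13[d][0], jj = j + DIR13[d][1], kk = k + DIR13[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int lj = levmap[(size_t)ii + (size_t)nx * (jj + (size_t)ny * kk)];
      if (lj == 0) continue;
      out[GG * d + (li - 1) + (R_xlen_t)G * (lj - 1)] += 1.0;
      out[GG * d + (lj - 1) + (R_xlen_t)G * (li - 1)] += 1.0;
    }
  }
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = 0;
  out.attr("dim") = IntegerVector::create(G, G, 13);
  return out;
}

// Cyclic Jacobi eigenvalues of a small symmetric matrix (row-major, n x n).
static void jacobi_eigenvalues(std::vector<double>& S, int n,
                               std::vector<double>& ev) {
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) off += S[p * n + q] * S[p * n + q];
    if (off < 1e-24) break;
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) {
        double apq = S[p * n + q];
        if (std::fabs(apq) < 1e-18) continue;
        double app = S[p * n + p], aqq = S[q * n + q];
        double theta = (aqq - app) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < n; ++k) {
          double akp = S[k * n + p], akq = S[k * n + q];
          S[k * n + p] = c * akp - s * akq;
          S[k * n + q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; ++k) {
          double apk = S[p * n + k], aqk = S[q * n + k];
          S[p * n + k] = c * apk - s * aqk;
          S[q * n + k] = s * apk + c * aqk;
        }
      }
  }
  ev.resize(n);
  for (int i = 0; i < n; ++i) ev[i] = S[i * n + i];
}

// ---------------------------------------------------------------------------
// GLCM statistics: per-direction symmetric co-occurrence probabilities and
// the four curated statistics (JointEntropy, ClusterShade, Imc1, MCC),
// averaged over the directions that contain at least one pair. MCC uses the
// identity Q = (D^-1 P)^2 with D = diag(marginals): Q is similar to the
// symmetric S = D^-1/2 P D^-1/2 squared, so its eigenvalues are the squares
// of the (real) eigenvalues of S.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_glcm_stats(IntegerVector idx, IntegerVector lev,
                             IntegerVector dim, int G, bool want_mcc) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t m = idx.size();
  if ((R_xlen_t)g_levmap.size() < nvox) g_levmap.assign((size_t)nvox, 0);
  std::vector<int>& levmap = g_levmap;
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = lev[t];

  std::vector<double> counts((size_t)G * G * 13, 0.0);
  const size_t GG = (size_t)G * G;
  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t p = idx[t];
    int i = (int)(p % nx);
    int rest = (int)(p / nx);
    int j = rest % ny;
    int k = rest / ny;
    int li = lev[t];
    for (int d = 0; d < 13; ++d) {
      int ii = i + DIR13[d][0], jj = j + DIR13[d][1], kk = k + DIR13[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int lj = levmap[(size_t)ii + (size_t)nx * (jj + (size_t)ny * kk)];
      if (lj == 0) continue;
      counts[GG * d + (li - 1) + (size_t)G * (lj - 1)] += 1.0;
      counts[GG * d + (lj - 1) + (size_t)G * (li - 1)] += 1.0;
    }
  }
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = 0;

  const double LOG2 = std::log(2.0);
  double sum_je = 0, sum_cs = 0, sum_imc1 = 0, sum_mcc = 0;
  int ndir = 0;
  std::vector<double> p((size_t)G * G), px(G), S;
  std::vector<int> occ(G);
  std::vector<double> ev;
  for (int d = 0; d < 13; ++d) {
    double tot = 0;
    for (size_t u = 0; u < GG; ++u) tot += counts[GG * d + u];
    if (tot == 0) continue;
    ++ndir;
    for (size_t u = 0; u < GG; ++u) p[u] = counts[GG * d + u] / tot;
    for (int i = 0; i < G; ++i) {
      px[i] = 0;
      for (int j = 0; j < G; ++j) px[i] += p[(size_t)i + (size_t)G * j];
    }
    double je = 0, cs = 0, mui = 0;
    for (int i = 0; i < G; ++i) mui += (i + 1) * px[i];
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < G; ++j) {
        double pij = p[(size_t)i + (size_t)G * j];
        if (pij > 0) je -= pij * std::log(pij) / LOG2;
        double dd = (i + 1) + (j + 1) - 2 * mui;
        cs += dd * dd * dd * pij;
      }
    double hx = 0;
    for (int i = 0; i < G; ++i) if (px[i] > 0) hx -= px[i] * std::log(px[i]) / LOG2;
    double hxy1 = 0;
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < G; ++j) {
        double pij = p[(size_t)i + (size_t)G * j];
        if (pij > 0) hxy1 -= pij * std::log(px[i] * px[j]) / LOG2;
      }
    double imc1 = hx > 0 ? (je - hxy1) / hx : 0.0;
    sum_je += je; sum_cs += cs; sum_imc1 += imc1;
    if (want_mcc) {
      int ng = 0;
      for (int i = 0; i < G; ++i) if (px[i] > 0) occ[ng++] = i;
      double mcc;
      if (ng < 2) {
        mcc = 1.0;
      } else {
        S.assign((size_t)ng * ng, 0.0);
        for (int a = 0; a < ng; ++a)
          for (int b = 0; b < ng; ++b)
            S[(size_t)a * ng + b] =
              p[(size_t)occ[a] + (size_t)G * occ[b]] /
              std::sqrt(px[occ[a]] * px[occ[b]]);
        jacobi_eigenvalues(S, ng, ev);
        for (auto& v : ev) v = std::fabs(v);
        std::sort(ev.begin(), ev.end(), std::greater<double>());
        mcc = ev[1];
        if (mcc > 1) mcc = 1;
        if (mcc < 0) mcc = 0;
      }
      sum_mcc += mcc;
    }
  }
  NumericVector out = NumericVector::create(
    _["JointEntropy"] = 0.0, _["ClusterShade"] = 0.0,
    _["Imc1"] = 0.0, _["MCC"] = 1.0);
  if (ndir > 0) {
    out[0] = sum_je / ndir;
    out[1] = sum_cs / ndir;
    out[2] = sum_imc1 / ndir;
    out[3] = want_mcc ? sum_mcc / ndir : NA_REAL;
  }
  return out;
}

// ---------------------------------------------------------------------------
// NGTDM accumulation with 26-connectivity; neighbours outside the region are
// excluded from the neighbourhood mean ("valid neighbours" rule). Returns a
// G x 2 matrix: column 1 the voxel count n_i per level, column 2 the summed
// absolute deviation s_i. Voxels with zero valid neighbours contribute to
// n_i but add nothing to s_i.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector idx, IntegerVector lev, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t m = idx.size();
  if ((R_xlen_t)g_levmap.size() < nvox) g_levmap.assign((size_t)nvox, 0);
  std::vector<int>& levmap = g_levmap;
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = lev[t];

  NumericMatrix out(G, 2);
  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t p = idx[t];
    int i = (int)(p % nx);
    int rest = (int)(p / nx);
    int j = rest % ny;
    int k = rest / ny;
    int li = lev[t];
    double sum = 0.0;
    int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          int lj = levmap[(size_t)ii + (size_t)nx * (jj + (size_t)ny * kk)];
          if (lj == 0) continue;
          sum += lj;
          ++cnt;
        }
    out(li - 1, 0) += 1.0;
    if (cnt > 0) out(li - 1, 1) += std::fabs((double)li - sum / cnt);
  }
  for (R_xlen_t t = 0; t < m; ++t) levmap[(size_t)idx[t]] = 0;
  return out;
}

// ---------------------------------------------------------------------------
// Batched texture statistics: one filtered volume, many band voxel-index
// sets. For each band: min-anchored discretization at the given bin width,
// then the requested GLCM statistics, NGTDM busyness and first-order
// minimum. Columns: JointEntropy, ClusterShade, Imc1, MCC, Busyness, Min.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_texture_batch(NumericVector x, IntegerVector dim,
                                List idx_list, double bin_width,
                                bool want_glcm, bool want_mcc,
                                bool want_busy, bool want_min) {
  const int nspec = idx_list.size();
  NumericMatrix out(nspec, 6);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int s = 0; s < nspec; ++s) {
    IntegerVector idx = idx_list[s];
    const R_xlen_t m = idx.size();
    if (m == 0) continue;
    double mn = x[idx[0]], mx = x[idx[0]];
    for (R_xlen_t t = 1; t < m; ++t) {
      double v = x[idx[t]];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (want_min) out(s, 5) = mn;
    IntegerVector lev(m);
    int G = 1;
    for (R_xlen_t t = 0; t < m; ++t) {
      int l = (int)std::floor((x[idx[t]] - mn) / bin_width) + 1;
      lev[t] = l;
      if (l > G) G = l;
    }
    if (G == 1) {
      if (want_glcm) { out(s, 0) = 0; out(s, 1) = 0; out(s, 2) = 0; out(s, 3) = 1; }
      if (want_busy) out(s, 4) = 0;
      continue;
    }
    if (want_glcm) {
      NumericVector st = cpp_glcm_stats(idx, lev, dim, G, want_mcc);
      out(s, 0) = st[0]; out(s, 1) = st[1]; out(s, 2) = st[2]; out(s, 3) = st[3];
    }
    if (want_busy) {
      NumericMatrix nm = cpp_ngtdm(idx, lev, dim, G);
      double N = 0;
      for (int i = 0; i < G; ++i) N += nm(i, 0);
      double num = 0, den = 0;
      for (int i = 0; i < G; ++i) {
        double pi = nm(i, 0) / N;
        num += pi * nm(i, 1);
        if (pi <= 0) continue;
        for (int j = 0; j < G; ++j) {
          double pj = nm(j, 0) / N;
          if (pj <= 0) continue;
          den += std::fabs((i + 1) * pi - (j + 1) * pj);
        }
      }
      out(s, 4) = den == 0 ? 0.0 : num / den;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with symmetric (half-sample mirror) boundary.
// For a kernel h of length L the anchor is c = (L - 1) / 2 (integer division)
// and y[i] = sum_t h[t] * x[i + c - t]. Kernels of length 1 skip the pass.
// ---------------------------------------------------------------------------

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline int wrap(int i, int n) {
  i %= n;
  if (i < 0) i += n;
  return i;
}

static void conv_axis(std::vector<double>& x, int nx, int ny, int nz,
                      const NumericVector& h, int axis, int boundary) {
  const int L = h.size();
  if (L == 1 && h[0] == 1.0) return;
  const int c = (L - 1) / 2;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride;
  int n, m1, m2;
  R_xlen_t s1, s2;
  if (axis == 0)      { stride = sx; n = nx; m1 = ny; m2 = nz; s1 = sy; s2 = sz; }
  else if (axis == 1) { stride = sy; n = ny; m1 = nx; m2 = nz; s1 = sx; s2 = sz; }
  else                { stride = sz; n = nz; m1 = nx; m2 = ny; s1 = sx; s2 = sy; }
  std::vector<double> line(n), res(n);
  for (int b = 0; b < m2; ++b)
    for (int a = 0; a < m1; ++a) {
      R_xlen_t base = s1 * a + s2 * b;
      for (int q = 0; q < n; ++q) line[q] = x[base + stride * q];
      for (int q = 0; q < n; ++q) {
        double acc = 0.0;
        if (boundary == 1)
          for (int t = 0; t < L; ++t) acc += h[t] * line[wrap(q + c - t, n)];
        else
          for (int t = 0; t < L; ++t) acc += h[t] * line[reflect(q + c - t, n)];
        res[q] = acc;
      }
      for (int q = 0; q < n; ++q) x[base + stride * q] = res[q];
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector x, IntegerVector dim,
                           NumericVector kx, NumericVector ky, NumericVector kz,
                           int boundary) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(x.begin(), x.end());
  conv_axis(buf, nx, ny, nz, kx, 0, boundary);
  conv_axis(buf, nx, ny, nz, ky, 1, boundary);
  conv_axis(buf, nx, ny, nz, kz, 2, boundary);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}
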