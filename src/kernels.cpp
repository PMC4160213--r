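// Voxel kernels for wallfibril3d.
//
// All volumes are passed as flat numeric vectors with dims d = (d0, d1, d2)
// where d0 (the array z axis, beam direction) varies fastest:
//   linear index = z + d0 * (y + d1 * x).
// Physical coordinates: nm = 0-based index * voxel_size.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 style boundary: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void conv1d_axis(std::vector<double> &v, int d0, int d1, int d2,
                        int axis, const std::vector<double> &kern) {
  const int r = (int)kern.size() / 2;
  int n, stride, nlines, la, lb;
  if (axis == 0)      { n = d0; stride = 1;        }
  else if (axis == 1) { n = d1; stride = d0;       }
  else                { n = d2; stride = d0 * d1;  }
  // iterate over all lines orthogonal to 'axis'
  if (axis == 0)      { la = d1; lb = d2; }
  else if (axis == 1) { la = d0; lb = d2; }
  else                { la = d0; lb = d1; }
  nlines = la * lb;
  const int w = 2 * r + 1;
  std::vector<double> buf(n + 2 * r);
  const double *kp = kern.data();
  for (int line = 0; line < nlines; ++line) {
    int a = line % la, b = line / la;
    long base;
    if (axis == 0)      base = (long)d0 * (a + (long)d1 * b);
    else if (axis == 1) base = a + (long)d0 * d1 * b;
    else                base = a + (long)d0 * b;
    double *bp = buf.data() + r;
    for (int i = 0; i < n; ++i) bp[i] = v[base + (long)i * stride];
    for (int k = 1; k <= r; ++k) {              // reflect-101 padding
      bp[-k] = bp[reflect_idx(-k, n)];
      bp[n - 1 + k] = bp[reflect_idx(n - 1 + k, n)];
    }
    for (int i = 0; i < n; ++i) {
      const double *src = bp + i - r;
      double s = 0.0;
      for (int k = 0; k < w; ++k) s += kp[k] * src[k];
      v[base + (long)i * stride] = s;
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &x : k) x /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) {
    if (sigma[a] > 1e-12) {
      std::vector<double> k = gauss_kernel(sigma[a]);
      conv1d_axis(v, d0, d1, d2, a, k);
    }
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// central differences with reflect boundary (zero slope at edges)
static void grad_axis(const std::vector<double> &v, std::vector<double> &g,
                      int d0, int d1, int d2, int axis) {
  long n = (long)d0 * d1 * d2;
  g.assign(n, 0.0);
  int na = (axis == 0) ? d0 : (axis == 1 ? d1 : d2);
  long stride = (axis == 0) ? 1 : (axis == 1 ? d0 : (long)d0 * d1);
  for (int x = 0; x < d2; ++x)
    for (int y = 0; y < d1; ++y)
      for (int z = 0; z < d0; ++z) {
        long i = z + (long)d0 * (y + (long)d1 * x);
        int c = (axis == 0) ? z : (axis == 1 ? y : x);
        double hi = (c + 1 < na) ? v[i + stride] : v[i - (na > 1 ? stride : 0)];
        double lo = (c - 1 >= 0) ? v[i - stride] : v[i + (na > 1 ? stride : 0)];
        // at boundaries reflect-101 gives (v[1]-v[1])/2 = 0 gradient; use
        // one-sided neighbor reflection consistent with conv boundary
        if (c + 1 >= na) hi = v[i - (na > 1 ? stride : 0)];
        if (c - 1 < 0)   lo = v[i + (na > 1 ? stride : 0)];
        g[i] = 0.5 * (hi - lo);
      }
}

// ---- symmetric 3x3 eigendecomposition (analytic) ----------------------------

struct Eig3 {
  double lam[3];       // descending
  double vec[3][3];    // vec[k] is eigenvector for lam[k]
};

static inline void cross3(const double a[3], const double b[3], double c[3]) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double a[3]) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}
static inline void normalize3(double a[3]) {
  double n = norm3(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}

// eigenvector for eigenvalue lam of symmetric A given by rows
static bool eigvec_for(const double A[3][3], double lam, double v[3]) {
  double r0[3] = {A[0][0] - lam, A[0][1], A[0][2]};
  double r1[3] = {A[0][1], A[1][1] - lam, A[1][2]};
  double r2[3] = {A[0][2], A[1][2], A[2][2] - lam};
  double c01[3], c02[3], c12[3];
  cross3(r0, r1, c01); cross3(r0, r2, c02); cross3(r1, r2, c12);
  double n01 = norm3(c01), n02 = norm3(c02), n12 = norm3(c12);
  double *best = c01; double nb = n01;
  if (n02 > nb) { best = c02; nb = n02; }
  if (n12 > nb) { best = c12; nb = n12; }
  if (nb < 1e-30) return false;
  v[0] = best[0] / nb; v[1] = best[1] / nb; v[2] = best[2] / nb;
  return true;
}

// prev_v3: used for deterministic tie-breaking when lam2 ~ lam3
static void eig_sym3(double a00, double a01, double a02, double a11,
                     double a12, double a22, const double prev_v3[3],
                     Eig3 &e) {
  double A[3][3] = {{a00, a01, a02}, {a01, a11, a12}, {a02, a12, a22}};
  double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  double scale = std::fabs(a00) + std::fabs(a11) + std::fabs(a22) + 2 * std::sqrt(p1);
  if (scale < 1e-300) scale = 1.0;
  if (p1 < 1e-24 * scale * scale) {
    // diagonal: sort eigenvalues, eigenvectors are coordinate axes
    int ord[3] = {0, 1, 2};
    double d[3] = {a00, a11, a22};
    for (int i = 0; i < 2; ++i)
      for (int j = i + 1; j < 3; ++j)
        if (d[ord[j]] > d[ord[i]]) std::swap(ord[i], ord[j]);
    for (int k = 0; k < 3; ++k) {
      e.lam[k] = d[ord[k]];
      e.vec[k][0] = e.vec[k][1] = e.vec[k][2] = 0.0;
      e.vec[k][ord[k]] = 1.0;
    }
  } else {
    double q = (a00 + a11 + a22) / 3.0;
    double p2 = (a00 - q) * (a00 - q) + (a11 - q) * (a11 - q) +
                (a22 - q) * (a22 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double B[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        B[i][j] = (A[i][j] - (i == j ? q : 0.0)) / p;
    double detB = B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
                  B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
                  B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    e.lam[0] = q + 2.0 * p * std::cos(phi);
    e.lam[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e.lam[1] = 3.0 * q - e.lam[0] - e.lam[2];
    if (!eigvec_for(A, e.lam[0], e.vec[0])) {
      e.vec[0][0] = 1; e.vec[0][1] = 0; e.vec[0][2] = 0;
    }
    double tol = 1e-9 * (std::fabs(e.lam[0]) + 1.0);
    if (e.lam[1] - e.lam[2] < tol) {
      // degenerate minor plane: pick v3 in the plane orthogonal to v1,
      // most aligned with prev_v3 (reproducible raster-order convention)
      double p3[3] = {prev_v3[0], prev_v3[1], prev_v3[2]};
      double dp = p3[0] * e.vec[0][0] + p3[1] * e.vec[0][1] + p3[2] * e.vec[0][2];
      double cand[3] = {p3[0] - dp * e.vec[0][0], p3[1] - dp * e.vec[0][1],
                        p3[2] - dp * e.vec[0][2]};
      if (norm3(cand) < 1e-12) {
        // prev parallel to v1: take coordinate axis least aligned with v1
        int k = 0; double best = std::fabs(e.vec[0][0]);
        for (int j = 1; j < 3; ++j)
          if (std::fabs(e.vec[0][j]) < best) { best = std::fabs(e.vec[0][j]); k = j; }
        cand[0] = cand[1] = cand[2] = 0.0; cand[k] = 1.0;
        dp = cand[0] * e.vec[0][0] + cand[1] * e.vec[0][1] + cand[2] * e.vec[0][2];
        cand[0] -= dp * e.vec[0][0]; cand[1] -= dp * e.vec[0][1]; cand[2] -= dp * e.vec[0][2];
      }
      normalize3(cand);
      e.vec[2][0] = cand[0]; e.vec[2][1] = cand[1]; e.vec[2][2] = cand[2];
    } else if (!eigvec_for(A, e.lam[2], e.vec[2])) {
      e.vec[2][0] = 0; e.vec[2][1] = 0; e.vec[2][2] = 1;
    }
    cross3(e.vec[2], e.vec[0], e.vec[1]);
    normalize3(e.vec[1]);
  }
  // sign convention: first nonzero component positive
  for (int k = 0; k < 3; ++k) {
    double *v = e.vec[k];
    for (int j = 0; j < 3; ++j) {
      if (std::fabs(v[j]) > 1e-12) {
        if (v[j] < 0) { v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2]; }
        break;
      }
    }
  }
}

// build the 6 smoothed structure-tensor channels of v
static void tensor_channels(const std::vector<double> &v, int d0, int d1, int d2,
                            double sigma_d, double sigma_w,
                            std::vector<double> J[6]) {
  long n = (long)d0 * d1 * d2;
  std::vector<double> us(v);
  if (sigma_d > 1e-12) {
    std::vector<double> k = gauss_kernel(sigma_d);
    for (int a = 0; a < 3; ++a) conv1d_axis(us, d0, d1, d2, a, k);
  }
  std::vector<double> g0, g1, g2;
  grad_axis(us, g0, d0, d1, d2, 0);
  grad_axis(us, g1, d0, d1, d2, 1);
  grad_axis(us, g2, d0, d1, d2, 2);
  for (int c = 0; c < 6; ++c) J[c].resize(n);
  for (long i = 0; i < n; ++i) {
    J[0][i] = g0[i] * g0[i];
    J[1][i] = g0[i] * g1[i];
    J[2][i] = g0[i] * g2[i];
    J[3][i] = g1[i] * g1[i];
    J[4][i] = g1[i] * g2[i];
    J[5][i] = g2[i] * g2[i];
  }
  if (sigma_w > 1e-12) {
    std::vector<double> k = gauss_kernel(sigma_w);
    for (int c = 0; c < 6; ++c)
      for (int a = 0; a < 3; ++a) conv1d_axis(J[c], d0, d1, d2, a, k);
  }
}

// [[Rcpp::export]]
List cpp_structure_tensor(NumericVector vol, IntegerVector dim,
                          double sigma_d, double sigma_w) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> J[6];
  tensor_channels(v, d0, d1, d2, sigma_d, sigma_w, J);
  NumericMatrix lam(n, 3), v1(n, 3), v3(n, 3);
  double prev[3] = {0.0, 1.0, 0.0};
  Eig3 e;
  for (long i = 0; i < n; ++i) {
    eig_sym3(J[0][i], J[1][i], J[2][i], J[3][i], J[4][i], J[5][i], prev, e);
    for (int k = 0; k < 3; ++k) {
      lam(i, k) = e.lam[k];
      v1(i, k) = e.vec[0][k];
      v3(i, k) = e.vec[2][k];
    }
    prev[0] = e.vec[2][0]; prev[1] = e.vec[2][1]; prev[2] = e.vec[2][2];
  }
  return List::create(_["lambda"] = lam, _["v1"] = v1, _["v3"] = v3);
}

// ---- nonlinear anisotropic diffusion ---------------------------------------

// [[Rcpp::export]]
NumericVector cpp_nad(NumericVector vol, IntegerVector dim, int iterations,
                      double time_step, double K, double sigma_d,
                      double sigma_w, int hybrid) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  std::vector<double> u(vol.begin(), vol.end());
  std::vector<double> J[6], D[6], P0, P1, P2, unew(n);
  double prev[3] = {0.0, 1.0, 0.0};
  Eig3 e;
  const long s0 = 1, s1 = d0, s2 = (long)d0 * d1;

  for (int it = 0; it < iterations; ++it) {
    tensor_channels(u, d0, d1, d2, sigma_d, sigma_w, J);
    for (int c = 0; c < 6; ++c) D[c].resize(n);
    for (long i = 0; i < n; ++i) {
      eig_sym3(J[0][i], J[1][i], J[2][i], J[3][i], J[4][i], J[5][i], prev, e);
      prev[0] = e.vec[2][0]; prev[1] = e.vec[2][1]; prev[2] = e.vec[2][2];
      bool coh = hybrid && (e.lam[1] - e.lam[2]) > (e.lam[0] - e.lam[1]);
      if (coh) {
        // coherence-enhancing branch: diffuse mainly along the filament (v3)
        const double alpha = 0.05;
        const double *v = e.vec[2];
        D[0][i] = alpha + (1 - alpha) * v[0] * v[0];
        D[1][i] = (1 - alpha) * v[0] * v[1];
        D[2][i] = (1 - alpha) * v[0] * v[2];
        D[3][i] = alpha + (1 - alpha) * v[1] * v[1];
        D[4][i] = (1 - alpha) * v[1] * v[2];
        D[5][i] = alpha + (1 - alpha) * v[2] * v[2];
      } else {
        // edge-enhancing: Weickert exponent-8 stopping function across v1
        double c2 = e.lam[0] - e.lam[2];
        double contrast = c2 > 0 ? std::sqrt(c2) : 0.0;
        double g = 1.0;
        if (contrast > 0) {
          double x = contrast / K;
          double x2 = x * x, x4 = x2 * x2, x8 = x4 * x4;
          g = 1.0 - std::exp(-3.315 / x8);
        }
        const double *v = e.vec[0];
        D[0][i] = 1.0 + (g - 1.0) * v[0] * v[0];
        D[1][i] = (g - 1.0) * v[0] * v[1];
        D[2][i] = (g - 1.0) * v[0] * v[2];
        D[3][i] = 1.0 + (g - 1.0) * v[1] * v[1];
        D[4][i] = (g - 1.0) * v[1] * v[2];
        D[5][i] = 1.0 + (g - 1.0) * v[2] * v[2];
      }
    }
    grad_axis(u, P0, d0, d1, d2, 0);
    grad_axis(u, P1, d0, d1, d2, 1);
    grad_axis(u, P2, d0, d1, d2, 2);
    std::copy(u.begin(), u.end(), unew.begin());
    // face fluxes, zero at domain boundary: exact conservation by telescoping
    for (int x = 0; x < d2; ++x)
      for (int y = 0; y < d1; ++y)
        for (int z = 0; z < d0; ++z) {
          long i = z + s1 * y + s2 * x;
          if (z + 1 < d0) {
            long j = i + s0;
            double F = 0.5 * (D[0][i] + D[0][j]) * (u[j] - u[i]) +
                       0.25 * (D[1][i] + D[1][j]) * (P1[i] + P1[j]) +
                       0.25 * (D[2][i] + D[2][j]) * (P2[i] + P2[j]);
            unew[i] += time_step * F;
            unew[j] -= time_step * F;
          }
          if (y + 1 < d1) {
            long j = i + s1;
            double F = 0.25 * (D[1][i] + D[1][j]) * (P0[i] + P0[j]) +
                       0.5 * (D[3][i] + D[3][j]) * (u[j] - u[i]) +
                       0.25 * (D[4][i] + D[4][j]) * (P2[i] + P2[j]);
            unew[i] += time_step * F;
            unew[j] -= time_step * F;
          }
          if (x + 1 < d2) {
            long j = i + s2;
            double F = 0.25 * (D[2][i] + D[2][j]) * (P0[i] + P0[j]) +
                       0.25 * (D[4][i] + D[4][j]) * (P1[i] + P1[j]) +
                       0.5 * (D[5][i] + D[5][j]) * (u[j] - u[i]);
            unew[i] += time_step * F;
            unew[j] -= time_step * F;
          }
        }
    std::swap(u, unew);
    for (long i = 0; i < n; ++i)
      if (!std::isfinite(u[i]))
        stop("nad_filter: non-finite value at iteration %d", it + 1);
  }
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dim;
  return out;
}

// ---- anisotropic orientation smoothing -------------------------------------

// [[Rcpp::export]]
NumericVector cpp_orient_smooth(NumericVector vol, IntegerVector dim,
                                NumericMatrix v3, double sigma_along,
                                double sigma_across) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  int R = std::max(1, (int)std::ceil(3.0 * sigma_along));
  NumericVector out(n);
  out.attr("dim") = dim;
  const double isa = 1.0 / (2.0 * sigma_along * sigma_along);
  const double isc = sigma_across > 1e-9
                       ? 1.0 / (2.0 * sigma_across * sigma_across) : -1.0;
  for (int x = 0; x < d2; ++x)
    for (int y = 0; y < d1; ++y)
      for (int z = 0; z < d0; ++z) {
        long i = z + (long)d0 * (y + (long)d1 * x);
        double e0 = v3(i, 0), e1 = v3(i, 1), e2 = v3(i, 2);
        double sw = 0.0, sv = 0.0;
        int z0 = std::max(0, z - R), z1 = std::min(d0 - 1, z + R);
        int y0 = std::max(0, y - R), y1 = std::min(d1 - 1, y + R);
        int x0 = std::max(0, x - R), x1 = std::min(d2 - 1, x + R);
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy)
            for (int zz = z0; zz <= z1; ++zz) {
              double dz = zz - z, dy = yy - y, dx = xx - x;
              double t = dz * e0 + dy * e1 + dx * e2;
              double r2 = dz * dz + dy * dy + dx * dx - t * t;
              if (r2 < 0) r2 = 0;
              double w;
              if (isc < 0) {
                if (r2 > 0.25) continue;
                w = std::exp(-t * t * isa);
              } else {
                w = std::exp(-t * t * isa - r2 * isc);
              }
              sw += w;
              sv += w * vol[zz + (long)d0 * (yy + (long)d1 * xx)];
            }
        out[i] = sv / sw;
      }
  return out;
}

// ---- connected components ---------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim,
                          int connectivity) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<long> offs;
  std::vector<int> oz, oy, ox;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        if (connectivity == 18 && m > 2) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int z = p % d0, y = (p / d0) % d1, x = p / ((long)d0 * d1);
      for (size_t k = 0; k < oz.size(); ++k) {
        int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
        if (zz < 0 || zz >= d0 || yy < 0 || yy >= d1 || xx < 0 || xx >= d2)
          continue;
        long q = zz + (long)d0 * (yy + (long)d1 * xx);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ---- squared Euclidean distance transform (Felzenszwalb) --------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vtx, std::vector<double> &zenv, int n) {
  int k = 0;
  vtx[0] = 0;
  zenv[0] = -1e30;
  zenv[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[vtx[k]] + vtx[k] * (double)vtx[k])) /
               (2.0 * q - 2.0 * vtx[k]);
    while (s <= zenv[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[vtx[k]] + vtx[k] * (double)vtx[k])) /
          (2.0 * q - 2.0 * vtx[k]);
    }
    ++k;
    vtx[k] = q;
    zenv[k] = s;
    zenv[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zenv[k + 1] < q) ++k;
    double dq = q - (double)vtx[k];
    d[q] = dq * dq + f[vtx[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim) {
  // distance (in voxels) from each foreground voxel center to the nearest
  // background voxel center; 0 on background
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  const double BIG = 1e30;
  std::vector<double> v(n);
  for (long i = 0; i < n; ++i) v[i] = mask[i] ? BIG : 0.0;
  int nmax = std::max(d0, std::max(d1, d2));
  std::vector<double> f(nmax), dbuf(nmax), zenv(nmax + 1);
  std::vector<int> vtx(nmax);
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int na = (axis == 0) ? d0 : (axis == 1 ? d1 : d2);
    long stride = (axis == 0) ? 1 : (axis == 1 ? d0 : (long)d0 * d1);
    int la = (axis == 0) ? d1 : d0;
    int lb = (axis == 2) ? d1 : d2;
    for (int b = 0; b < lb; ++b)
      for (int a = 0; a < la; ++a) {
        long base;
        if (axis == 0)      base = (long)d0 * (a + (long)d1 * b);
        else if (axis == 1) base = a + (long)d0 * d1 * b;
        else                base = a + (long)d0 * b;
        for (int i = 0; i < na; ++i) f[i] = v[base + (long)i * stride];
        dt1d(f, dbuf, vtx, zenv, na);
        for (int i = 0; i < na; ++i) v[base + (long)i * stride] = dbuf[i];
      }
  }
  NumericVector out(n);
  out.attr("dim") = dim;
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(v[i] > 1e29 ? 1e29 : v[i]);
  return out;
}

// ---- topology-preserving thinning ------------------------------------------

// local 3x3x3 neighborhood extracted as bool[27], index = (dz+1) + 3*(dy+1) + 9*(dx+1)
static inline int nb_index(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

static void get_neighborhood(const std::vector<unsigned char> &m, int d0,
                             int d1, int d2, int z, int y, int x,
                             bool nb[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = false;
        if (zz >= 0 && zz < d0 && yy >= 0 && yy < d1 && xx >= 0 && xx < d2)
          v = m[zz + (long)d0 * (yy + (long)d1 * xx)] != 0;
        nb[nb_index(dz, dy, dx)] = v;
      }
}

// number of 26-connected components of foreground in N26 (center excluded)
static int count_fg_components26(const bool nb[27]) {
  bool fg[27];
  for (int i = 0; i < 27; ++i) fg[i] = nb[i];
  fg[nb_index(0, 0, 0)] = false;
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!fg[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int pz = p % 3 - 1, py = (p / 3) % 3 - 1, px = p / 9 - 1;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = pz + dz, yy = py + dy, xx = px + dx;
            if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1)
              continue;
            int q = nb_index(zz, yy, xx);
            if (fg[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
          }
    }
  }
  return comp;
}

// number of 6-connected components of background restricted to N18 that are
// 6-adjacent to the center
static int count_bg_components6(const bool nb[27]) {
  bool bg[27];
  for (int i = 0; i < 27; ++i) {
    int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
    int m = std::abs(z) + std::abs(y) + std::abs(x);
    bg[i] = (m >= 1 && m <= 2) && !nb[i];  // N18, background only
  }
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!bg[s] || seen[s]) continue;
    // only seed from the 6 face neighbors (components must touch center)
    int z = s % 3 - 1, y = (s / 3) % 3 - 1, x = s / 9 - 1;
    if (std::abs(z) + std::abs(y) + std::abs(x) != 1) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int pz = p % 3 - 1, py = (p / 3) % 3 - 1, px = p / 9 - 1;
      const int f[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int zz = pz + f[k][0], yy = py + f[k][1], xx = px + f[k][2];
        if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1)
          continue;
        int q = nb_index(zz, yy, xx);
        if (bg[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
      }
    }
  }
  return comp;
}

static inline bool is_simple(const bool nb[27]) {
  return count_fg_components26(nb) == 1 && count_bg_components6(nb) == 1;
}

static inline int count_fg26(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (nb[i]) ++c;
  if (nb[nb_index(0, 0, 0)]) --c;
  return c;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  std::vector<unsigned char> m(n);
  for (long i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  // direction order U,D,N,S,E,W mapped to -z,+z,-y,+y,+x,-x borders
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, 1}, {0, 0, -1}};
  bool nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      int dz = dirs[d][0], dy = dirs[d][1], dx = dirs[d][2];
      for (int x = 0; x < d2; ++x)
        for (int y = 0; y < d1; ++y)
          for (int z = 0; z < d0; ++z) {
            long i = z + (long)d0 * (y + (long)d1 * x);
            if (!m[i]) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            bool bgdir = !(zz >= 0 && zz < d0 && yy >= 0 && yy < d1 &&
                           xx >= 0 && xx < d2 &&
                           m[zz + (long)d0 * (yy + (long)d1 * xx)]);
            if (bgdir) cand.push_back(i);
          }
      // delete sequentially (raster order), re-testing at deletion time:
      // each deletion removes a currently-simple point, so topology is
      // preserved by construction
      for (long i : cand) {
        int z = i % d0, y = (i / d0) % d1, x = i / ((long)d0 * d1);
        get_neighborhood(m, d0, d1, d2, z, y, x, nb);
        int nfg = count_fg26(nb);
        if (nfg <= 1) continue;              // endpoint or isolated: keep
        if (!is_simple(nb)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  IntegerVector out(n);
  out.attr("dim") = dim;
  for (long i = 0; i < n; ++i) out[i] = m[i];
  return out;
}

// ---- capsule rasterization --------------------------------------------------

// segs columns: z0,y0,x0,z1,y1,x1 (nm), radius (nm), level
// soft edge: density ramps from level to 0 over one voxel, surface (level/2)
// at distance = radius; combined by max so overlaps do not double density
// [[Rcpp::export]]
NumericVector cpp_add_capsules(NumericVector vol, IntegerVector dim,
                               NumericMatrix segs, double voxel_size) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector out = clone(vol);
  out.attr("dim") = dim;
  for (int s = 0; s < segs.nrow(); ++s) {
    double z0 = segs(s, 0), y0 = segs(s, 1), x0 = segs(s, 2);
    double z1 = segs(s, 3), y1 = segs(s, 4), x1 = segs(s, 5);
    double r = segs(s, 6), level = segs(s, 7);
    double pad = r + 1.0 * voxel_size;
    int zlo = std::max(0, (int)std::floor((std::min(z0, z1) - pad) / voxel_size));
    int zhi = std::min(d0 - 1, (int)std::ceil((std::max(z0, z1) + pad) / voxel_size));
    int ylo = std::max(0, (int)std::floor((std::min(y0, y1) - pad) / voxel_size));
    int yhi = std::min(d1 - 1, (int)std::ceil((std::max(y0, y1) + pad) / voxel_size));
    int xlo = std::max(0, (int)std::floor((std::min(x0, x1) - pad) / voxel_size));
    int xhi = std::min(d2 - 1, (int)std::ceil((std::max(x0, x1) + pad) / voxel_size));
    double az = z1 - z0, ay = y1 - y0, ax = x1 - x0;
    double len2 = az * az + ay * ay + ax * ax;
    for (int x = xlo; x <= xhi; ++x)
      for (int y = ylo; y <= yhi; ++y)
        for (int z = zlo; z <= zhi; ++z) {
          double pz = z * voxel_size, py = y * voxel_size, px = x * voxel_size;
          double t = 0.0;
          if (len2 > 0) {
            t = ((pz - z0) * az + (py - y0) * ay + (px - x0) * ax) / len2;
            if (t < 0) t = 0;
            if (t > 1) t = 1;
          }
          double qz = z0 + t * az, qy = y0 + t * ay, qx = x0 + t * ax;
          double dd = std::sqrt((pz - qz) * (pz - qz) + (py - qy) * (py - qy) +
                                (px - qx) * (px - qx));
          double val = level * std::min(1.0, std::max(0.0, (r - dd) / voxel_size + 0.5));
          long i = z + (long)d0 * (y + (long)d1 * x);
          if (val > out[i]) out[i] = val;
        }
  }
  return out;
}

// ---- contour spectrum helpers ----------------------------------------------

// per isovalue: foreground voxel count, internal fg|bg face count, mean
// gradient magnitude over boundary foreground voxels
// [[Rcpp::export]]
NumericMatrix cpp_contour_stats(NumericVector vol, IntegerVector dim,
                                NumericVector isovalues) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long n = (long)d0 * d1 * d2;
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> g0, g1, g2;
  grad_axis(v, g0, d0, d1, d2, 0);
  grad_axis(v, g1, d0, d1, d2, 1);
  grad_axis(v, g2, d0, d1, d2, 2);
  std::vector<double> gm(n);
  for (long i = 0; i < n; ++i)
    gm[i] = std::sqrt(g0[i] * g0[i] + g1[i] * g1[i] + g2[i] * g2[i]);
  int ni = isovalues.size();
  NumericMatrix out(ni, 3);
  const long s0 = 1, s1 = d0, s2 = (long)d0 * d1;
  for (int k = 0; k < ni; ++k) {
    double iso = isovalues[k];
    long fg = 0, faces = 0, nbnd = 0;
    double gsum = 0.0;
    for (int x = 0; x < d2; ++x)
      for (int y = 0; y < d1; ++y)
        for (int z = 0; z < d0; ++z) {
          long i = z + s1 * y + s2 * x;
          bool fi = v[i] > iso;
          if (fi) ++fg;
          bool bnd = false;
          if (z + 1 < d0) { bool fj = v[i + s0] > iso; if (fi != fj) { ++faces; bnd = bnd || fi; } }
          if (y + 1 < d1) { bool fj = v[i + s1] > iso; if (fi != fj) { ++faces; bnd = bnd || fi; } }
          if (x + 1 < d2) { bool fj = v[i + s2] > iso; if (fi != fj) { ++faces; bnd = bnd || fi; } }
          if (fi && !bnd) {
            if ((z > 0 && !(v[i - s0] > iso)) || (y > 0 && !(v[i - s1] > iso)) ||
                (x > 0 && !(v[i - s2] > iso)))
              bnd = true;
          }
          if (fi && bnd) { ++nbnd; gsum += gm[i]; }
        }
    out(k, 0) = (double)fg / (double)n;
    out(k, 1) = (double)faces;
    out(k, 2) = nbnd > 0 ? gsum / nbnd : 0.0;
  }
  return out;
}
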