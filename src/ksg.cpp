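#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Copy an n x d column-major R matrix into a row-major buffer so the
// per-pair distance loops touch contiguous memory.
static std::vector<double> row_major(const NumericMatrix& m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<double> out((size_t)n * d);
  for (int c = 0; c < d; ++c)
    for (int r = 0; r < n; ++r)
      out[(size_t)r * d + c] = m(r, c);
  return out;
}

static inline double cheb_row(const double* a, const double* b, int d) {
  double dist = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = std::fabs(a[c] - b[c]);
    if (v > dist) dist = v;
  }
  return dist;
}

// Kraskov-Stoegbauer-Grassberger / Frenzel-Pompe conditional mutual
// information I(Y; X | Z) in nats, estimated with k nearest neighbours
// under the max-norm. Rows of y, x, z are joint observations.
//
// For each point: eps_i = Chebyshev distance to the k-th nearest
// neighbour in the joint (y, x, z) space; n_xz, n_yz, n_z count the other
// points strictly within eps_i in the respective marginal spaces. Then
//   I = psi(k) + mean( psi(n_z + 1) - psi(n_xz + 1) - psi(n_yz + 1) ).
// Brute-force O(n^2); intended for series of a few thousand points.
// [[Rcpp::export]]
double ksg_cmi_cpp(NumericMatrix y, NumericMatrix x, NumericMatrix z,
                   int k) {
  const int n = y.nrow();
  if (x.nrow() != n || z.nrow() != n)
    stop("y, x, z must have the same number of rows");
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");
  const int dy = y.ncol(), dx = x.ncol(), dz = z.ncol();

  const std::vector<double> ry = row_major(y), rx = row_major(x),
                            rz = row_major(z);
  std::vector<double> dxz(n), dyz(n), dz_(n), joint(n), tmp(n);
  double acc = 0.0;

  for (int i = 0; i < n; ++i) {
    const double* yi = &ry[(size_t)i * dy];
    const double* xi = &rx[(size_t)i * dx];
    const double* zi = &rz[(size_t)i * dz];
    for (int j = 0; j < n; ++j) {
      if (j == i) { joint[j] = R_PosInf; continue; }
      const double d_z = cheb_row(zi, &rz[(size_t)j * dz], dz);
      const double d_x = cheb_row(xi, &rx[(size_t)j * dx], dx);
      const double d_y = cheb_row(yi, &ry[(size_t)j * dy], dy);
      dz_[j] = d_z;
      dxz[j] = d_x > d_z ? d_x : d_z;
      dyz[j] = d_y > d_z ? d_y : d_z;
      joint[j] = dxz[j] > dyz[j] ? dxz[j] : dyz[j];
    }
    // distance to the k-th nearest neighbour in the joint space
    std::copy(joint.begin(), joint.end(), tmp.begin());
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];

    int n_xz = 0, n_yz = 0, n_z = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dxz[j] < eps) ++n_xz;
      if (dyz[j] < eps) ++n_yz;
      if (dz_[j] < eps) ++n_z;
    }
    acc += R::digamma(n_z + 1.0) - R::digamma(n_xz + 1.0)
         - R::digamma(n_yz + 1.0);
  }
  return R::digamma((double)k) + acc / n;
}
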