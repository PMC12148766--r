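#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Count sample points falling inside a union of tetrahedra.
//
// verts: V x 3 mapped vertex coordinates (mm)
// tets:  T x 4 1-based vertex indices
// pts:   N x 3 sample points
//
// Each tetrahedron is tested via barycentric coordinates from a precomputed
// inverse edge matrix; points on faces (within a small tolerance) count as
// hits, a measure-zero convention fixed for determinism. Tetrahedra are
// binned into a uniform grid over the global bounding box so each point only
// tests nearby candidates.
// [[Rcpp::export]]
int hitmiss_hits(NumericMatrix verts, IntegerMatrix tets, NumericMatrix pts) {
  const int T = tets.nrow(), N = pts.nrow();
  if (T == 0 || N == 0) return 0;

  std::vector<double> v0(3 * T), inv(9 * T), blo(3 * T), bhi(3 * T);
  std::vector<bool> ok(T, true);

  double glo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double ghi[3] = {R_NegInf, R_NegInf, R_NegInf};

  for (int t = 0; t < T; ++t) {
    double p[4][3];
    for (int c = 0; c < 4; ++c) {
      int vi = tets(t, c) - 1;
      for (int d = 0; d < 3; ++d) p[c][d] = verts(vi, d);
    }
    double e[3][3];  // columns = edge vectors p1-p0, p2-p0, p3-p0
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) e[d][c] = p[c + 1][d] - p[0][d];
    double det =
        e[0][0] * (e[1][1] * e[2][2] - e[1][2] * e[2][1]) -
        e[0][1] * (e[1][0] * e[2][2] - e[1][2] * e[2][0]) +
        e[0][2] * (e[1][0] * e[2][1] - e[1][1] * e[2][0]);
    if (std::fabs(det) < 1e-300) { ok[t] = false; continue; }
    double id = 1.0 / det;
    // inverse (row-major): adj(e)^T scaled
    inv[9 * t + 0] = (e[1][1] * e[2][2] - e[1][2] * e[2][1]) * id;
    inv[9 * t + 1] = (e[0][2] * e[2][1] - e[0][1] * e[2][2]) * id;
    inv[9 * t + 2] = (e[0][1] * e[1][2] - e[0][2] * e[1][1]) * id;
    inv[9 * t + 3] = (e[1][2] * e[2][0] - e[1][0] * e[2][2]) * id;
    inv[9 * t + 4] = (e[0][0] * e[2][2] - e[0][2] * e[2][0]) * id;
    inv[9 * t + 5] = (e[0][2] * e[1][0] - e[0][0] * e[1][2]) * id;
    inv[9 * t + 6] = (e[1][0] * e[2][1] - e[1][1] * e[2][0]) * id;
    inv[9 * t + 7] = (e[0][1] * e[2][0] - e[0][0] * e[2][1]) * id;
    inv[9 * t + 8] = (e[0][0] * e[1][1] - e[0][1] * e[1][0]) * id;
    for (int d = 0; d < 3; ++d) {
      v0[3 * t + d] = p[0][d];
      double lo = p[0][d], hi = p[0][d];
      for (int c = 1; c < 4; ++c) {
        if (p[c][d] < lo) lo = p[c][d];
        if (p[c][d] > hi) hi = p[c][d];
      }
      blo[3 * t + d] = lo; bhi[3 * t + d] = hi;
      if (lo < glo[d]) glo[d] = lo;
      if (hi > ghi[d]) ghi[d] = hi;
    }
  }

  // spatial binning
  int nb = (int)std::ceil(std::cbrt((double)T / 4.0));
  if (nb < 1) nb = 1;
  if (nb > 64) nb = 64;
  double cell[3], span[3];
  for (int d = 0; d < 3; ++d) {
    span[d] = ghi[d] - glo[d];
    if (span[d] <= 0) span[d] = 1e-12;
    cell[d] = span[d] / nb;
  }
  std::vector< std::vector<int> > bins((size_t)nb * nb * nb);
  for (int t = 0; t < T; ++t) {
    if (!ok[t]) continue;
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)((blo[3 * t + d] - glo[d]) / cell[d]); if (lo[d] < 0) lo[d] = 0; if (lo[d] >= nb) lo[d] = nb - 1;
      hi[d] = (int)((bhi[3 * t + d] - glo[d]) / cell[d]); if (hi[d] < 0) hi[d] = 0; if (hi[d] >= nb) hi[d] = nb - 1;
    }
    for (int a = lo[0]; a <= hi[0]; ++a)
      for (int b = lo[1]; b <= hi[1]; ++b)
        for (int c = lo[2]; c <= hi[2]; ++c)
          bins[(size_t)a + (size_t)nb * b + (size_t)nb * nb * c].push_back(t);
  }

  const double eps = 1e-10;
  int hits = 0;
  for (int i = 0; i < N; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int ci[3];
    bool outside = false;
    for (int d = 0; d < 3; ++d) {
      ci[d] = (int)((q[d] - glo[d]) / cell[d]);
      if (q[d] < glo[d] || q[d] > ghi[d]) { outside = true; break; }
      if (ci[d] < 0) ci[d] = 0;
      if (ci[d] >= nb) ci[d] = nb - 1;
    }
    if (outside) continue;
    const std::vector<int>& cand = bins[(size_t)ci[0] + (size_t)nb * ci[1] + (size_t)nb * nb * ci[2]];
    for (size_t c = 0; c < cand.size(); ++c) {
      int t = cand[c];
      const double* b0 = &blo[3 * t];
      const double* b1 = &bhi[3 * t];
      if (q[0] < b0[0] || q[0] > b1[0] || q[1] < b0[1] || q[1] > b1[1] ||
          q[2] < b0[2] || q[2] > b1[2]) continue;
      double r[3] = {q[0] - v0[3 * t], q[1] - v0[3 * t + 1], q[2] - v0[3 * t + 2]};
      const double* M = &inv[9 * t];
      double l1 = M[0] * r[0] + M[1] * r[1] + M[2] * r[2];
      if (l1 < -eps || l1 > 1 + eps) continue;
      double l2 = M[3] * r[0] + M[4] * r[1] + M[5] * r[2];
      if (l2 < -eps || l1 + l2 > 1 + eps) continue;
      double l3 = M[6] * r[0] + M[7] * r[1] + M[8] * r[2];
      if (l3 >= -eps && l1 + l2 + l3 <= 1 + eps) { ++hits; break; }
    }
  }
  return hits;
}
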