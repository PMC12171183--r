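#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson 3D Delaunay triangulation.
// Expects points in (near-)general position; the R wrapper applies a
// deterministic sub-resolution jitter before calling, because voxel-grid
// clouds are cospherical almost everywhere.

namespace {

struct Tet {
  int v[4];
  double c[3];   // circumcenter
  double r2;     // squared circumradius
  bool alive;
};

inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// circumsphere of p0..p3; returns false on a degenerate (flat) tetrahedron
bool circumsphere(const std::vector<std::array<double, 3> >& P,
                  const int* v, double* c, double& r2) {
  const double* p0 = P[v[0]].data();
  double A[3][3], b[3];
  for (int k = 0; k < 3; ++k) {
    const double* pk = P[v[k + 1]].data();
    double n2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      A[k][d] = 2.0 * (pk[d] - p0[d]);
      n2 += pk[d] * pk[d] - p0[d] * p0[d];
    }
    b[k] = n2;
  }
  double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  // Cramer's rule
  double x[3];
  for (int col = 0; col < 3; ++col) {
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) M[i][j] = (j == col) ? b[i] : A[i][j];
    double dcol =
        M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
        M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
        M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    x[col] = dcol / det;
  }
  c[0] = x[0]; c[1] = x[1]; c[2] = x[2];
  r2 = dist2(c, p0);
  return std::isfinite(r2);
}

} // namespace

// [[Rcpp::export(name = ".delaunay3_cpp")]]
IntegerMatrix delaunay3_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<std::array<double, 3> > P(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (!std::isfinite(v)) stop("non-finite coordinate");
      P[i][d] = v;
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  double ctr[3], span = 0.0;
  for (int d = 0; d < 3; ++d) {
    ctr[d] = 0.5 * (lo[d] + hi[d]);
    span = std::max(span, hi[d] - lo[d]);
  }
  if (span <= 0.0) span = 1.0;
  const double B = 1000.0 * span;
  // super-tetrahedron enclosing everything
  const double sv[4][3] = {
    { 0.0,  0.0,  3.0}, { 2.82842712474619, 0.0, -1.0},
    {-1.414213562373095,  2.449489742783178, -1.0},
    {-1.414213562373095, -2.449489742783178, -1.0}};
  for (int k = 0; k < 4; ++k)
    for (int d = 0; d < 3; ++d) P[n + k][d] = ctr[d] + B * sv[k][d];

  std::vector<Tet> tets;
  tets.reserve(16 * (size_t)n + 64);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    t0.alive = true;
    if (!circumsphere(P, t0.v, t0.c, t0.r2)) stop("super-tetrahedron degenerate");
    tets.push_back(t0);
  }

  std::vector<int> bad;
  typedef std::array<int, 3> Face;
  std::map<Face, int> faceCount;

  for (int ip = 0; ip < n; ++ip) {
    const double* p = P[ip].data();
    bad.clear();
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      if (dist2(p, tets[t].c) <= tets[t].r2) bad.push_back(t);
    }
    if (bad.empty())
      stop("point outside all circumspheres (degenerate input; jitter the cloud)");
    faceCount.clear();
    static const int faceIdx[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tet& t = tets[bad[b]];
      for (int f = 0; f < 4; ++f) {
        Face fa = {t.v[faceIdx[f][0]], t.v[faceIdx[f][1]], t.v[faceIdx[f][2]]};
        std::sort(fa.begin(), fa.end());
        ++faceCount[fa];
      }
      tets[bad[b]].alive = false;
    }
    for (std::map<Face, int>::const_iterator it = faceCount.begin();
         it != faceCount.end(); ++it) {
      if (it->second != 1) continue;  // interior face of the cavity
      Tet nt;
      nt.v[0] = it->first[0]; nt.v[1] = it->first[1];
      nt.v[2] = it->first[2]; nt.v[3] = ip;
      nt.alive = true;
      if (!circumsphere(P, nt.v, nt.c, nt.r2)) {
        // flat cavity face through the new point: keep with infinite sphere so
        // a later insertion destroys it; harmless for jittered input
        nt.r2 = R_PosInf;
        nt.c[0] = nt.c[1] = nt.c[2] = 0.0;
      }
      tets.push_back(nt);
    }
    // compact occasionally so the brute-force scan stays near the live count
    if (tets.size() > 64 && (ip & 255) == 255) {
      std::vector<Tet> keep;
      keep.reserve(tets.size());
      for (size_t t = 0; t < tets.size(); ++t)
        if (tets[t].alive) keep.push_back(tets[t]);
      tets.swap(keep);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (tets[t].v[k] >= n) { super = true; break; }
    if (!super) ++m;
  }
  IntegerMatrix out(m, 4);
  int row = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (tets[t].v[k] >= n) { super = true; break; }
    if (super) continue;
    for (int k = 0; k < 4; ++k) out(row, k) = tets[t].v[k] + 1;
    ++row;
  }
  return out;
}
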