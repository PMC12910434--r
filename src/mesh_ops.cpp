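#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericMatrix cp(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) { vx[i]=V(i,0); vy[i]=V(i,1); vz[i]=V(i,2); }
  // face bounding boxes for pruning
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf), bz0(nf), bz1(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
    bx0[f] = std::min({vx[i0],vx[i1],vx[i2]}); bx1[f] = std::max({vx[i0],vx[i1],vx[i2]});
    by0[f] = std::min({vy[i0],vy[i1],vy[i2]}); by1[f] = std::max({vy[i0],vy[i1],vy[i2]});
    bz0[f] = std::min({vz[i0],vz[i1],vz[i2]}); bz1[f] = std::max({vz[i0],vz[i1],vz[i2]});
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = R_PosInf;
    double bestpt[3] = {0,0,0};
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      // lower bound on squared distance from box
      double dx = std::max({bx0[f]-p[0], 0.0, p[0]-bx1[f]});
      double dy = std::max({by0[f]-p[1], 0.0, p[1]-by1[f]});
      double dz = std::max({bz0[f]-p[2], 0.0, p[2]-bz1[f]});
      double lb = dx*dx + dy*dy + dz*dz;
      if (lb >= best) continue;
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      double a[3] = {vx[i0], vy[i0], vz[i0]};
      double b[3] = {vx[i1], vy[i1], vz[i1]};
      double c[3] = {vx[i2], vy[i2], vz[i2]};
      double q[3];
      closest_on_tri(p, a, b, c, q);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) d2 += (q[k]-p[k])*(q[k]-p[k]);
      if (d2 < best) {
        best = d2; bestf = f;
        for (int k = 0; k < 3; ++k) bestpt[k] = q[k];
      }
    }
    cp(i,0)=bestpt[0]; cp(i,1)=bestpt[1]; cp(i,2)=bestpt[2];
    dist[i] = std::sqrt(best);
    face[i] = bestf + 1;
  }
  return List::create(_["point"] = cp, _["dist"] = dist, _["face"] = face);
}

// z values where the vertical line through (x,y) crosses the surface
static void column_crossings(double x, double y,
                             const NumericMatrix &V, const IntegerMatrix &F,
                             std::vector<double> &zs) {
  zs.clear();
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
    double ax = V(i0,0)-x, ay = V(i0,1)-y;
    double bx = V(i1,0)-x, by = V(i1,1)-y;
    double cx = V(i2,0)-x, cy = V(i2,1)-y;
    // 2D barycentric sign test in the xy plane
    double d1 = ax*by - ay*bx;
    double d2 = bx*cy - by*cx;
    double d3 = cx*ay - cy*ax;
    bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
    bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
    if (has_neg && has_pos) continue;   // outside projected triangle
    double denom = d1 + d2 + d3;
    if (denom == 0.0) continue;         // degenerate projection
    double w0 = d2 / denom, w1 = d3 / denom, w2 = d1 / denom;
    zs.push_back(w0 * V(i0,2) + w1 * V(i1,2) + w2 * V(i2,2));
  }
  std::sort(zs.begin(), zs.end());
}

// [[Rcpp::export]]
List cpp_column_crossings(NumericMatrix V, IntegerMatrix F,
                          NumericVector x, NumericVector y) {
  int n = x.size();
  List out(n);
  std::vector<double> zs;
  for (int i = 0; i < n; ++i) {
    column_crossings(x[i], y[i], V, F, zs);
    out[i] = NumericVector(zs.begin(), zs.end());
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F, double jitter) {
  int np = P.nrow();
  LogicalVector inside(np);
  std::vector<double> zs;
  for (int i = 0; i < np; ++i) {
    // deterministic tiny jitter avoids rays through edges/vertices
    double x = P(i,0) + jitter, y = P(i,1) + 2.0 * jitter;
    column_crossings(x, y, V, F, zs);
    int above = 0;
    for (size_t k = 0; k < zs.size(); ++k) if (zs[k] > P(i,2)) ++above;
    inside[i] = (above % 2) == 1;
  }
  return inside;
}
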