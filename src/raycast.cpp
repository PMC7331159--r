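#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore intersection of a full line (negative t allowed) with one
// triangle. Returns true and fills t on a hit; near-parallel rays miss.
static inline bool line_tri(const double *o, const double *d,
                            const double *v0, const double *v1,
                            const double *v2, double &t) {
  const double EPS = 1e-12;
  double e1[3], e2[3], p[3], q[3], s[3];
  for (int i = 0; i < 3; ++i) { e1[i] = v1[i] - v0[i]; e2[i] = v2[i] - v0[i]; }
  p[0] = d[1]*e2[2] - d[2]*e2[1];
  p[1] = d[2]*e2[0] - d[0]*e2[2];
  p[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) s[i] = o[i] - v0[i];
  double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return false;
  q[0] = s[1]*e1[2] - s[2]*e1[1];
  q[1] = s[2]*e1[0] - s[0]*e1[2];
  q[2] = s[0]*e1[1] - s[1]*e1[0];
  double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return false;
  t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
  return true;
}

// All intersection parameters t (sorted ascending) of each line
// origin[i] + t * dir[i] with the mesh (V: nv x 3, F: nf x 3 one-based).
// Returns a list of numeric vectors, one per line.
// [[Rcpp::export]]
List cpp_line_mesh_hits(NumericMatrix origins, NumericMatrix dirs,
                        NumericMatrix V, IntegerMatrix F) {
  int nr = origins.nrow(), nf = F.nrow();
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3*i + j] = V(i, j);
  List out(nr);
  std::vector<double> hits;
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r,0), origins(r,1), origins(r,2)};
    double d[3] = {dirs(r,0), dirs(r,1), dirs(r,2)};
    hits.clear();
    for (int f = 0; f < nf; ++f) {
      double t;
      const double *v0 = &vx[3*(F(f,0)-1)];
      const double *v1 = &vx[3*(F(f,1)-1)];
      const double *v2 = &vx[3*(F(f,2)-1)];
      if (line_tri(o, d, v0, v1, v2, t)) hits.push_back(t);
    }
    std::sort(hits.begin(), hits.end());
    // collapse duplicate hits from shared triangle edges
    std::vector<double> uniq;
    for (double t : hits)
      if (uniq.empty() || t - uniq.back() > 1e-9) uniq.push_back(t);
    out[r] = NumericVector(uniq.begin(), uniq.end());
  }
  return out;
}

// First hit with t > tmin along each ray; NA when the ray misses.
// [[Rcpp::export]]
NumericVector cpp_ray_mesh_first(NumericMatrix origins, NumericMatrix dirs,
                                 NumericMatrix V, IntegerMatrix F,
                                 double tmin) {
  int nr = origins.nrow(), nf = F.nrow();
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3*i + j] = V(i, j);
  NumericVector out(nr, NA_REAL);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r,0), origins(r,1), origins(r,2)};
    double d[3] = {dirs(r,0), dirs(r,1), dirs(r,2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double t;
      const double *v0 = &vx[3*(F(f,0)-1)];
      const double *v1 = &vx[3*(F(f,1)-1)];
      const double *v2 = &vx[3*(F(f,2)-1)];
      if (line_tri(o, d, v0, v1, v2, t) && t > tmin && t < best) best = t;
    }
    if (R_finite(best)) out[r] = best;
  }
  return out;
}

// Index (one-based) of the nearest row of B for every row of A.
// [[Rcpp::export]]
IntegerVector cpp_nearest_rows(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double best = R_PosInf; int bi = 1;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = j + 1; }
    }
    idx[i] = bi;
  }
  return idx;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

// closest point on the mesh surface for every query point (nq x 3)
// [[Rcpp::export]]
NumericMatrix cpp_closest_on_mesh(NumericMatrix Q, NumericMatrix V,
                                  IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow();
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3*i + j] = V(i, j);
  NumericMatrix out(nq, 3);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q,0), Q(q,1), Q(q,2)};
    double best = R_PosInf, bp[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      double cand[3];
      closest_on_tri(p, &vx[3*(F(f,0)-1)], &vx[3*(F(f,1)-1)],
                     &vx[3*(F(f,2)-1)], cand);
      double d2 = 0;
      for (int i = 0; i < 3; ++i) d2 += (p[i]-cand[i])*(p[i]-cand[i]);
      if (d2 < best) { best = d2; for (int i=0;i<3;++i) bp[i]=cand[i]; }
    }
    for (int i = 0; i < 3; ++i) out(q, i) = bp[i];
  }
  return out;
}
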