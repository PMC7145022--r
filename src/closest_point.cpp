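#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, via barycentric region tests
// (Ericson, Real-Time Collision Detection, 5.1.5). Writes result into out.
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".closest_points_cpp")]]
List closest_points_cpp(NumericMatrix queries, NumericMatrix vertices,
                        IntegerMatrix triangles) {
  const int nq = queries.nrow();
  const int nt = triangles.nrow();
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector tri(nq);

  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = vertices(i, j);
  std::vector<int> F(nt * 3);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) F[3 * i + j] = triangles(i, j) - 1;

  double q[3], cand[3], best[3];
  for (int iq = 0; iq < nq; ++iq) {
    q[0] = queries(iq, 0); q[1] = queries(iq, 1); q[2] = queries(iq, 2);
    double bestd2 = R_PosInf;
    int bestt = -1;
    for (int it = 0; it < nt; ++it) {
      const double *a = &V[3 * F[3 * it]];
      const double *b = &V[3 * F[3 * it + 1]];
      const double *c = &V[3 * F[3 * it + 2]];
      closest_on_triangle(q, a, b, c, cand);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double dd = cand[i] - q[i];
        d2 += dd * dd;
      }
      if (d2 < bestd2) {
        bestd2 = d2;
        bestt = it;
        best[0] = cand[0]; best[1] = cand[1]; best[2] = cand[2];
      }
    }
    pts(iq, 0) = best[0]; pts(iq, 1) = best[1]; pts(iq, 2) = best[2];
    dist[iq] = std::sqrt(bestd2);
    tri[iq] = bestt + 1;
  }
  return List::create(_["point"] = pts, _["distance"] = dist,
                      _["triangle"] = tri);
}
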