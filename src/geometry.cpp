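#include <Rcpp.h>
#include <cfloat>
#include <cmath>

using namespace Rcpp;

// Nearest vertex in `ref` for every row of `query`. Brute force; meshes in
// this package are a few thousand vertices, so O(N*M) in C++ is well under
// interactive latency and avoids any tie-break ambiguity (lowest index wins).
// [[Rcpp::export(name = ".nn_bruteforce")]]
List nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = DBL_MAX;
    int bestj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = ref(j, 0) - qx;
      double d = dx * dx;
      if (d >= best) continue;
      const double dy = ref(j, 1) - qy;
      d += dy * dy;
      if (d >= best) continue;
      const double dz = ref(j, 2) - qz;
      d += dz * dz;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, 5.1.5). Writes result into out[3], returns squared distance.
static inline double closest_on_tri(const double *p, const double *a,
                                    const double *b, const double *c,
                                    double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    } else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        const double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
        const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
        } else {
          const double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            const double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
          } else {
            const double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
            } else {
              const double denom = 1.0 / (va + vb + vc);
              const double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
            }
          }
        }
      }
    }
  }
  const double dx = p[0] - out[0], dy = p[1] - out[1], dz = p[2] - out[2];
  return dx * dx + dy * dy + dz * dz;
}

// For every query point, the closest point on the triangulated surface
// (V, F). F is 1-based. Brute force over triangles with a per-triangle
// bounding-box reject against the current best distance; queries are seeded
// with the nearest-vertex distance so most triangles are culled early.
// [[Rcpp::export(name = ".closest_on_surface")]]
List closest_on_surface(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  const int n = query.nrow(), nf = F.nrow(), nv = V.nrow();

  // Pre-extract triangle vertices and bounding boxes.
  std::vector<double> ta(3 * nf), tb(3 * nf), tc(3 * nf);
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      const double va = V(ia, k), vb = V(ib, k), vc = V(ic, k);
      ta[3 * f + k] = va; tb[3 * f + k] = vb; tc[3 * f + k] = vc;
      blo[3 * f + k] = std::min(va, std::min(vb, vc));
      bhi[3 * f + k] = std::max(va, std::max(vb, vc));
    }
  }

  NumericMatrix closest(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n);

  for (int i = 0; i < n; ++i) {
    double p[3] = { query(i, 0), query(i, 1), query(i, 2) };

    // Seed with nearest-vertex distance (upper bound on surface distance).
    double best = DBL_MAX;
    for (int j = 0; j < nv; ++j) {
      const double dx = V(j, 0) - p[0], dy = V(j, 1) - p[1], dz = V(j, 2) - p[2];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    best += 1e-12;

    double bestpt[3] = { p[0], p[1], p[2] };
    int bestf = 0;
    double out[3];
    for (int f = 0; f < nf; ++f) {
      // box reject: squared distance from p to the triangle's AABB
      double dbox = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double lo = blo[3 * f + k], hi = bhi[3 * f + k];
        double e = 0.0;
        if (p[k] < lo) e = lo - p[k];
        else if (p[k] > hi) e = p[k] - hi;
        dbox += e * e;
      }
      if (dbox > best) continue;
      const double d = closest_on_tri(p, &ta[3 * f], &tb[3 * f], &tc[3 * f], out);
      if (d < best) {
        best = d;
        bestpt[0] = out[0]; bestpt[1] = out[1]; bestpt[2] = out[2];
        bestf = f;
      }
    }
    closest(i, 0) = bestpt[0];
    closest(i, 1) = bestpt[1];
    closest(i, 2) = bestpt[2];
    dist[i] = std::sqrt(std::max(best, 0.0));
    tri[i] = bestf + 1;
  }
  return List::create(_["closest"] = closest, _["distance"] = dist,
                      _["triangle"] = tri);
}
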