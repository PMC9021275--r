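#include <Rcpp.h>
#include "fields.h"

using namespace Rcpp;

// Batched evaluation of the regularized-Stokeslet velocity field u and the
// fluid angular velocity w = (1/2) curl u at arbitrary target points, for a
// system of point forces and point torques.  eps may vary per source.
// With wall = true the exact image system for a no-slip plane at z = 0 is
// added (all sources and targets must then have z > 0).
// [[Rcpp::export]]
List cpp_fluid_fields(NumericMatrix targets, NumericMatrix src,
                      NumericMatrix force, NumericMatrix torque,
                      NumericVector eps, double mu,
                      bool wall, bool want_w) {
  int m = targets.nrow(), n = src.nrow();
  NumericMatrix U(m, 3), W(want_w ? m : 0, 3);
  double scale = 1.0 / (8.0 * M_PI * mu);
  for (int i = 0; i < m; ++i) {
    Vec3 x(targets(i, 0), targets(i, 1), targets(i, 2));
    Vec3 u, w;
    for (int j = 0; j < n; ++j) {
      Vec3 s(src(j, 0), src(j, 1), src(j, 2));
      Vec3 F(force(j, 0), force(j, 1), force(j, 2));
      Vec3 T(torque(j, 0), torque(j, 1), torque(j, 2));
      add_field(x, s, eps[j], F, T, u, w, want_w, wall);
    }
    U(i, 0) = u.x * scale; U(i, 1) = u.y * scale; U(i, 2) = u.z * scale;
    if (want_w) {
      W(i, 0) = w.x * scale; W(i, 1) = w.y * scale; W(i, 2) = w.z * scale;
    }
  }
  return List::create(_["u"] = U, _["w"] = W);
}

// Blob (cut-off) function value psi_eps(r).
// [[Rcpp::export]]
NumericVector cpp_blob_value(NumericVector r, double eps) {
  int n = r.size();
  NumericVector out(n);
  double e2 = eps * eps;
  for (int i = 0; i < n; ++i) {
    double q2 = r[i] * r[i] + e2;
    out[i] = 15.0 * e2 * e2 / (8.0 * M_PI * std::pow(q2, 3.5));
  }
  return out;
}
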