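#include <Rcpp.h>
#include "rigid_core.h"

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_rigid_solve(NumericMatrix Xb, NumericMatrix Z, double K,
                     NumericVector fb, NumericVector nb,
                     NumericMatrix Rot0, double tol, int maxit) {
  int n = Xb.nrow();
  std::vector<Vec3> xb(n), z(n);
  for (int i = 0; i < n; ++i) {
    xb[i] = Vec3(Xb(i,0), Xb(i,1), Xb(i,2));
    z[i] = Vec3(Z(i,0), Z(i,1), Z(i,2));
  }
  double R[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R[3*c + r] = Rot0(r, c);
  Vec3 T;
  int it = rigid_solve_core(n, xb.data(), z.data(), K,
                            Vec3(fb[0], fb[1], fb[2]), Vec3(nb[0], nb[1], nb[2]),
                            T, R, tol, maxit);
  NumericMatrix Rout(3, 3);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) Rout(r, c) = R[3*c + r];
  // residuals of the balance equations
  Vec3 rf(fb[0], fb[1], fb[2]), rt(nb[0], nb[1], nb[2]);
  for (int i = 0; i < n; ++i) {
    Vec3 RZ; mat3_vec(R, z[i], RZ);
    Vec3 Fb = (xb[i] - T - RZ) * K;
    rf += Fb;
    rt += cross(RZ, Fb);
  }
  return List::create(_["T"] = NumericVector::create(T.x, T.y, T.z),
                      _["Rot"] = Rout, _["iterations"] = it,
                      _["force_residual"] = norm(rf),
                      _["torque_residual"] = norm(rt));
}
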