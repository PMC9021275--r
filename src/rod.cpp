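#include <Rcpp.h>
#include "rod_core.h"

using namespace Rcpp;

static std::vector<Vec3> as_vec3(const NumericMatrix& M) {
  std::vector<Vec3> v(M.nrow());
  for (int i = 0; i < M.nrow(); ++i) v[i] = Vec3(M(i,0), M(i,1), M(i,2));
  return v;
}

static NumericMatrix to_mat(const std::vector<Vec3>& v) {
  NumericMatrix M(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    M(i,0) = v[i].x; M(i,1) = v[i].y; M(i,2) = v[i].z;
  }
  return M;
}

static std::vector<double> rowmajor(const NumericMatrix& M) {
  std::vector<double> v(M.nrow() * 3);
  for (int i = 0; i < M.nrow(); ++i)
    for (int k = 0; k < 3; ++k) v[3*i + k] = M(i, k);
  return v;
}

// Internal force/torque resultants at segment half points (Eqs of the
// constitutive law), plus measured strains and midpoint triads.
// [[Rcpp::export]]
List cpp_rod_resultants(NumericMatrix X, NumericMatrix D1, NumericMatrix D2,
                        NumericMatrix D3, double ds, NumericMatrix amod,
                        NumericMatrix bmod, NumericMatrix Om, NumericMatrix Gam,
                        double theta_c = M_PI) {
  int n = X.nrow();
  std::vector<Vec3> Xv = as_vec3(X), d1 = as_vec3(D1), d2 = as_vec3(D2), d3 = as_vec3(D3);
  std::vector<double> a = rowmajor(amod), b = rowmajor(bmod),
                      om = rowmajor(Om), gm = rowmajor(Gam);
  RodWork w; w.resize(n);
  rod_measure(n, Xv.data(), d1.data(), d2.data(), d3.data(), ds, w, theta_c);
  rod_resultants(n, a.data(), b.data(), om.data(), gm.data(), w);
  NumericMatrix strain(n - 1, 6);
  for (int j = 0; j < n - 1; ++j)
    for (int k = 0; k < 6; ++k) strain(j, k) = w.strain[6*j + k];
  return List::create(_["F"] = to_mat(w.Fh), _["N"] = to_mat(w.Nh),
                      _["strain"] = strain,
                      _["M1"] = to_mat(w.M1), _["M2"] = to_mat(w.M2),
                      _["M3"] = to_mat(w.M3));
}

// Force/torque densities at markers from half-point resultants.
// [[Rcpp::export]]
List cpp_rod_densities(NumericMatrix Fh, NumericMatrix Nh, NumericMatrix X,
                       double ds, NumericVector Fghost, NumericVector Nghost) {
  int n = X.nrow();
  std::vector<Vec3> Xv = as_vec3(X);
  RodWork w; w.resize(n);
  for (int j = 0; j < n - 1; ++j) {
    w.Fh[j] = Vec3(Fh(j,0), Fh(j,1), Fh(j,2));
    w.Nh[j] = Vec3(Nh(j,0), Nh(j,1), Nh(j,2));
  }
  rod_densities(n, Xv.data(), ds,
                Vec3(Fghost[0], Fghost[1], Fghost[2]),
                Vec3(Nghost[0], Nghost[1], Nghost[2]), w);
  return List::create(_["f"] = to_mat(w.f), _["n"] = to_mat(w.n));
}

// Discrete elastic energy of the rod.
// [[Rcpp::export]]
double cpp_rod_energy(NumericMatrix X, NumericMatrix D1, NumericMatrix D2,
                      NumericMatrix D3, double ds, NumericMatrix amod,
                      NumericMatrix bmod, NumericMatrix Om, NumericMatrix Gam,
                      double theta_c = M_PI) {
  int n = X.nrow();
  std::vector<Vec3> Xv = as_vec3(X), d1 = as_vec3(D1), d2 = as_vec3(D2), d3 = as_vec3(D3);
  std::vector<double> a = rowmajor(amod), b = rowmajor(bmod),
                      om = rowmajor(Om), gm = rowmajor(Gam);
  RodWork w; w.resize(n);
  rod_measure(n, Xv.data(), d1.data(), d2.data(), d3.data(), ds, w, theta_c);
  return rod_energy_core(n, ds, a.data(), b.data(), om.data(), gm.data(), w);
}
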