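#ifndef LOPHO_RIGID_CORE_H
#define LOPHO_RIGID_CORE_H

#include <vector>
#include "lopho_util.h"

// Solve the quasi-static rigid body balance for the capsule:
//   0 = fb + K sum_i (Xb_i - T - R Z_i)
//   0 = nb + K sum_i (R Z_i) x (Xb_i - T - R Z_i)
// Translation is eliminated in closed form; the rotation is found by Newton
// iteration on the torque balance, parameterized by an incremental rotation
// vector applied to the warm start.
//
// R is stored as 9 doubles, column-major.  Returns the number of iterations
// used, or -1 if the iteration did not converge.

inline void mat3_vec(const double* R, const Vec3& v, Vec3& out) {
  out.x = R[0]*v.x + R[3]*v.y + R[6]*v.z;
  out.y = R[1]*v.x + R[4]*v.y + R[7]*v.z;
  out.z = R[2]*v.x + R[5]*v.y + R[8]*v.z;
}

// apply the rotation exp(hat(delta)) to the columns of R (left multiply)
inline void rotate_matrix(double* R, const Vec3& delta) {
  double th = norm(delta);
  if (th < 1e-300) return;
  Vec3 n = delta * (1.0 / th);
  for (int c = 0; c < 3; ++c) {
    Vec3 col(R[3*c], R[3*c+1], R[3*c+2]);
    Vec3 rc = rotate_about(col, n, th);
    R[3*c] = rc.x; R[3*c+1] = rc.y; R[3*c+2] = rc.z;
  }
}

inline bool solve3(const double A[3][3], const Vec3& b, Vec3& x) {
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double inv = 1.0 / det;
  x.x = inv*( b.x*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
            - A[0][1]*(b.y*A[2][2]-A[1][2]*b.z)
            + A[0][2]*(b.y*A[2][1]-A[1][1]*b.z));
  x.y = inv*( A[0][0]*(b.y*A[2][2]-A[1][2]*b.z)
            - b.x*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
            + A[0][2]*(A[1][0]*b.z-b.y*A[2][0]));
  x.z = inv*( A[0][0]*(A[1][1]*b.z-b.y*A[2][1])
            - A[0][1]*(A[1][0]*b.z-b.y*A[2][0])
            + b.x*(A[1][0]*A[2][1]-A[1][1]*A[2][0]));
  return true;
}

inline int rigid_solve_core(int nb, const Vec3* Xb, const Vec3* Z, double K,
                            const Vec3& fb, const Vec3& nbq,
                            Vec3& T, double* R, double tol, int maxit) {
  // closed-form translation
  Vec3 xm;
  for (int i = 0; i < nb; ++i) xm += Xb[i];
  xm = xm * (1.0 / nb);
  T = xm + fb * (1.0 / (nb * K));
  // M' = sum Z_i W_i^T with W_i = Xb_i - T  (column-major Mp[c*3+r])
  double Mp[9] = {0,0,0,0,0,0,0,0,0};
  for (int i = 0; i < nb; ++i) {
    Vec3 W = Xb[i] - T;
    Mp[0] += Z[i].x*W.x; Mp[1] += Z[i].y*W.x; Mp[2] += Z[i].z*W.x;
    Mp[3] += Z[i].x*W.y; Mp[4] += Z[i].y*W.y; Mp[5] += Z[i].z*W.y;
    Mp[6] += Z[i].x*W.z; Mp[7] += Z[i].y*W.z; Mp[8] += Z[i].z*W.z;
  }
  // A = R M' with (M')_{l m} = sum Z_l W_m.  Store M' row-major: Mprm[l][m].
  double Mprm[3][3];
  Mprm[0][0] = Mp[0]; Mprm[1][0] = Mp[1]; Mprm[2][0] = Mp[2];
  Mprm[0][1] = Mp[3]; Mprm[1][1] = Mp[4]; Mprm[2][1] = Mp[5];
  Mprm[0][2] = Mp[6]; Mprm[1][2] = Mp[7]; Mprm[2][2] = Mp[8];

  // Globalization: the torque balance has spurious stationary branches, so
  // from a cold start first take the closed-form optimum of the orthogonal
  // Procrustes problem (largest eigenvector of Horn's 4x4 quaternion
  // matrix, by shifted power iteration) and keep whichever start has the
  // smaller residual.
  {
    const double (&S)[3][3] = Mprm;
    double Nq[4][4] = {
      {S[0][0]+S[1][1]+S[2][2], S[1][2]-S[2][1], S[2][0]-S[0][2], S[0][1]-S[1][0]},
      {S[1][2]-S[2][1], S[0][0]-S[1][1]-S[2][2], S[0][1]+S[1][0], S[2][0]+S[0][2]},
      {S[2][0]-S[0][2], S[0][1]+S[1][0], -S[0][0]+S[1][1]-S[2][2], S[1][2]+S[2][1]},
      {S[0][1]-S[1][0], S[2][0]+S[0][2], S[1][2]+S[2][1], -S[0][0]-S[1][1]+S[2][2]}};
    double shift = 0.0;
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) shift += std::fabs(S[r][c]);
    double v[4] = {1, 0.1, 0.1, 0.1};
    for (int it = 0; it < 80; ++it) {
      double nv[4];
      for (int r = 0; r < 4; ++r) {
        nv[r] = 2.0 * shift * v[r];
        for (int c = 0; c < 4; ++c) nv[r] += Nq[r][c] * v[c];
      }
      double nn = std::sqrt(nv[0]*nv[0]+nv[1]*nv[1]+nv[2]*nv[2]+nv[3]*nv[3]);
      if (nn < 1e-300) break;
      for (int r = 0; r < 4; ++r) v[r] = nv[r] / nn;
    }
    // rotation matrix of quaternion v (column-major)
    double qw = v[0], qx = v[1], qy = v[2], qz = v[3];
    double Rh[9] = {
      1-2*(qy*qy+qz*qz), 2*(qx*qy+qz*qw),   2*(qx*qz-qy*qw),
      2*(qx*qy-qz*qw),   1-2*(qx*qx+qz*qz), 2*(qy*qz+qx*qw),
      2*(qx*qz+qy*qw),   2*(qy*qz-qx*qw),   1-2*(qx*qx+qy*qy)};
    auto resid = [&](const double* Rm) {
      double A[3][3];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          A[r][c] = Rm[r]*Mprm[0][c] + Rm[3+r]*Mprm[1][c] + Rm[6+r]*Mprm[2][c];
      Vec3 cv(A[1][2]-A[2][1], A[2][0]-A[0][2], A[0][1]-A[1][0]);
      return norm(nbq + K * cv);
    };
    if (resid(Rh) < resid(R)) for (int k = 0; k < 9; ++k) R[k] = Rh[k];
  }
  for (int it = 0; it < maxit; ++it) {
    // A = R * M' (row-major)
    double A[3][3];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        A[r][c] = R[r] * Mprm[0][c] + R[3+r] * Mprm[1][c] + R[6+r] * Mprm[2][c];
    Vec3 cvec(A[1][2] - A[2][1], A[2][0] - A[0][2], A[0][1] - A[1][0]);
    Vec3 g = nbq + K * cvec;
    if (norm(g) <= tol) return it;
    // Jacobian of K*cvec wrt rotation vector: K (A - tr(A) I)
    double trA = A[0][0] + A[1][1] + A[2][2];
    double J[3][3];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        J[r][c] = K * (A[r][c] - (r == c ? trA : 0.0));
    Vec3 delta;
    if (!solve3(J, -g, delta)) return -1;
    // guard against huge steps far from the solution
    double dn = norm(delta);
    if (dn > 0.5) delta = delta * (0.5 / dn);
    rotate_matrix(R, delta);
  }
  return -1;
}

#endif
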