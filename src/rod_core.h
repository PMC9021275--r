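#ifndef LOPHO_ROD_CORE_H
#define LOPHO_ROD_CORE_H

#include <vector>
#include "lopho_util.h"

// Discrete Kirchhoff rod on a staggered grid: marker positions X_j and
// orthonormal triads {D1,D2,D3}_j at integer points, internal force F and
// torque N at half points, force/torque densities f, n back at markers.

struct Quat {
  double w, x, y, z;
};

inline Quat quat_normalize(Quat q) {
  double n = std::sqrt(q.w*q.w + q.x*q.x + q.y*q.y + q.z*q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
  return q;
}

// quaternion of the rotation A = T1 * T0^T taking triad 0 to triad 1
inline Quat quat_between_triads(const Vec3& a1, const Vec3& a2, const Vec3& a3,
                                const Vec3& b1, const Vec3& b2, const Vec3& b3) {
  // A = b1 a1^T + b2 a2^T + b3 a3^T
  double A[3][3] = {
    {b1.x*a1.x + b2.x*a2.x + b3.x*a3.x, b1.x*a1.y + b2.x*a2.y + b3.x*a3.y, b1.x*a1.z + b2.x*a2.z + b3.x*a3.z},
    {b1.y*a1.x + b2.y*a2.x + b3.y*a3.x, b1.y*a1.y + b2.y*a2.y + b3.y*a3.y, b1.y*a1.z + b2.y*a2.z + b3.y*a3.z},
    {b1.z*a1.x + b2.z*a2.x + b3.z*a3.x, b1.z*a1.y + b2.z*a2.y + b3.z*a3.y, b1.z*a1.z + b2.z*a2.z + b3.z*a3.z}};
  double tr = A[0][0] + A[1][1] + A[2][2];
  Quat q;
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q.w = 0.25 * s;
    q.x = (A[2][1] - A[1][2]) / s;
    q.y = (A[0][2] - A[2][0]) / s;
    q.z = (A[1][0] - A[0][1]) / s;
  } else if (A[0][0] > A[1][1] && A[0][0] > A[2][2]) {
    double s = std::sqrt(1.0 + A[0][0] - A[1][1] - A[2][2]) * 2.0;
    q.w = (A[2][1] - A[1][2]) / s;
    q.x = 0.25 * s;
    q.y = (A[0][1] + A[1][0]) / s;
    q.z = (A[0][2] + A[2][0]) / s;
  } else if (A[1][1] > A[2][2]) {
    double s = std::sqrt(1.0 + A[1][1] - A[0][0] - A[2][2]) * 2.0;
    q.w = (A[0][2] - A[2][0]) / s;
    q.x = (A[0][1] + A[1][0]) / s;
    q.y = 0.25 * s;
    q.z = (A[1][2] + A[2][1]) / s;
  } else {
    double s = std::sqrt(1.0 + A[2][2] - A[0][0] - A[1][1]) * 2.0;
    q.w = (A[1][0] - A[0][1]) / s;
    q.x = (A[0][2] + A[2][0]) / s;
    q.y = (A[1][2] + A[2][1]) / s;
    q.z = 0.25 * s;
  }
  return quat_normalize(q);
}

inline Vec3 quat_rotate(const Quat& q, const Vec3& v) {
  Vec3 u(q.x, q.y, q.z);
  Vec3 t = cross(u, v) * 2.0;
  return v + t * q.w + cross(u, t);
}

// principal square root of the rotation (half rotation), valid for angle < pi
inline Quat quat_half(const Quat& q) {
  Quat h = q;
  h.w += 1.0;
  return quat_normalize(h);
}

struct RodWork {
  std::vector<Vec3> Fh, Nh;            // resultants at half points
  std::vector<Vec3> M1, M2, M3;        // midpoint triads
  std::vector<Vec3> f, n;              // densities at markers
  std::vector<double> strain;          // 6 per segment (Om1,Om2,Om3,G1,G2,G3)
  void resize(int n_) {
    Fh.assign(n_ - 1, Vec3()); Nh.assign(n_ - 1, Vec3());
    M1.assign(n_ - 1, Vec3()); M2.assign(n_ - 1, Vec3()); M3.assign(n_ - 1, Vec3());
    f.assign(n_, Vec3()); n.assign(n_, Vec3());
    strain.assign(6 * (n_ - 1), 0.0);
  }
};

// measure discrete strains (Om-hat, Gamma-hat) and midpoint triads.
//
// The rotation between neighbouring triads is expressed as a rotation
// vector (theta * axis), so the restoring moments grow monotonically with
// the joint angle instead of saturating at 180 degrees like the raw
// centred-difference measure, and a uniform twist omega measures exactly
// omega.  With a continuity buffer `qcont` (one quaternion per segment,
// carried across steps) the angle is unwrapped past the antipode, so a
// severely folded joint (the wrapping hairpin concentrates in the soft
// hook at coarse spacings) cannot "skip a tooth"; the measure diverges as
// theta approaches 2 pi and is additionally stiffened beyond theta_c.
inline void rod_measure(int n, const Vec3* X,
                        const Vec3* D1, const Vec3* D2, const Vec3* D3,
                        double ds, RodWork& w, double theta_c = M_PI,
                        Quat* qcont = 0) {
  for (int j = 0; j < n - 1; ++j) {
    Quat q = quat_between_triads(D1[j], D2[j], D3[j], D1[j+1], D2[j+1], D3[j+1]);
    if (qcont) {
      const Quat& p = qcont[j];
      if (q.w * p.w + q.x * p.x + q.y * p.y + q.z * p.z < 0) {
        q.w = -q.w; q.x = -q.x; q.y = -q.y; q.z = -q.z;
      }
      qcont[j] = q;
    }
    double vn = std::sqrt(q.x*q.x + q.y*q.y + q.z*q.z);
    double theta = 2.0 * std::atan2(vn, q.w);   // in [0, 2 pi)
    Vec3 axis = vn > 1e-14 ? Vec3(q.x / vn, q.y / vn, q.z / vn) : Vec3(1, 0, 0);
    // midpoint triads: half of the continuous rotation
    double ha = 0.5 * theta;
    Quat qh;
    qh.w = std::cos(0.5 * ha);
    double s2 = std::sin(0.5 * ha);
    qh.x = axis.x * s2; qh.y = axis.y * s2; qh.z = axis.z * s2;
    Vec3 m1 = quat_rotate(qh, D1[j]);
    Vec3 m2 = quat_rotate(qh, D2[j]);
    Vec3 m3 = quat_rotate(qh, D3[j]);
    w.M1[j] = m1; w.M2[j] = m2; w.M3[j] = m3;
    Vec3 Xs = (X[j+1] - X[j]) * (1.0 / ds);
    // joint-angle stiffening beyond theta_c (inactive for resolved rods)
    double rpi = theta / theta_c;
    double r6 = rpi * rpi * rpi; r6 *= r6;
    double g = (theta / ds) / std::max(1.0 - r6, 0.02);
    w.strain[6*j + 0] = g * dot(axis, m1);   // Omega1-hat
    w.strain[6*j + 1] = g * dot(axis, m2);   // Omega2-hat
    w.strain[6*j + 2] = g * dot(axis, m3);   // Omega3-hat (twist)
    w.strain[6*j + 3] = dot(m1, Xs);    // Gamma1-hat (shear)
    w.strain[6*j + 4] = dot(m2, Xs);    // Gamma2-hat (shear)
    w.strain[6*j + 5] = dot(m3, Xs);    // Gamma3-hat (stretch)
  }
}

// constitutive resultants at half points; amod/bmod/Om/Gam are (n-1) x 3
// row-major [seg][component]
inline void rod_resultants(int n, const double* amod, const double* bmod,
                           const double* Om, const double* Gam, RodWork& w) {
  for (int j = 0; j < n - 1; ++j) {
    const double* s = &w.strain[6*j];
    w.Fh[j] = w.M1[j] * (bmod[3*j+0] * (s[3] - Gam[3*j+0]))
            + w.M2[j] * (bmod[3*j+1] * (s[4] - Gam[3*j+1]))
            + w.M3[j] * (bmod[3*j+2] * (s[5] - Gam[3*j+2]));
    w.Nh[j] = w.M1[j] * (amod[3*j+0] * (s[0] - Om[3*j+0]))
            + w.M2[j] * (amod[3*j+1] * (s[1] - Om[3*j+1]))
            + w.M3[j] * (amod[3*j+2] * (s[2] - Om[3*j+2]));
  }
}

// densities at markers; ghost values close the proximal end (motor) and the
// distal end is free (F = N = 0 beyond the last marker).
inline void rod_densities(int n, const Vec3* X, double ds,
                          const Vec3& Fghost, const Vec3& Nghost, RodWork& w) {
  double ids = 1.0 / ds;
  for (int j = 0; j < n; ++j) {
    Vec3 Fl = (j == 0) ? Fghost : w.Fh[j-1];
    Vec3 Fr = (j == n-1) ? Vec3() : w.Fh[j];
    Vec3 Nl = (j == 0) ? Nghost : w.Nh[j-1];
    Vec3 Nr = (j == n-1) ? Vec3() : w.Nh[j];
    w.f[j] = (Fr - Fl) * (-ids);
    Vec3 crossterm;
    if (j > 0)   crossterm += cross((X[j] - X[j-1]) * ids, Fl) * 0.5;
    if (j < n-1) crossterm += cross((X[j+1] - X[j]) * ids, Fr) * 0.5;
    w.n[j] = (Nr - Nl) * (-ids) - crossterm;
  }
}

inline double rod_energy_core(int n, double ds,
                              const double* amod, const double* bmod,
                              const double* Om, const double* Gam,
                              const RodWork& w) {
  double E = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    const double* s = &w.strain[6*j];
    for (int i = 0; i < 3; ++i) {
      double dO = s[i] - Om[3*j+i];
      double dG = s[3+i] - Gam[3*j+i];
      E += amod[3*j+i] * dO * dO + bmod[3*j+i] * dG * dG;
    }
  }
  return 0.5 * ds * E;
}

#endif
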