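#ifndef LOPHO_FIELDS_H
#define LOPHO_FIELDS_H

#include "lopho_util.h"
#include "wall_image_gen.h"

// Regularized Stokeslet / rotlet fields for the blob
//   psi_e(r) = 15 e^4 / (8 pi (r^2+e^2)^{7/2}).
// All contributions accumulate u and w = (1/2) curl u, both times 8*pi*mu;
// the caller divides by 8*pi*mu once at the end.

// Free-space contribution of a point force F and point torque T at `src`.
inline void add_free_field(const Vec3& target, const Vec3& src, double e,
                           const Vec3& F, const Vec3& T,
                           Vec3& u, Vec3& w, bool want_w) {
  Vec3 r = target - src;
  double r2 = dot(r, r);
  double e2 = e * e;
  double q2 = r2 + e2;
  double iq = 1.0 / std::sqrt(q2);       // single sqrt + division per pair
  double iq2 = iq * iq;
  double iq3 = iq * iq2;
  double iq5 = iq3 * iq2;
  // Stokeslet
  u += F * ((r2 + 2.0 * e2) * iq3) + r * (dot(F, r) * iq3);
  // rotlet
  double rotk = 0.5 * (2.0 * r2 + 5.0 * e2) * iq5;
  u += cross(T, r) * rotk;
  if (want_w) {
    // w from force: same rotlet structure by symmetry of (1/2) curl
    w += cross(F, r) * rotk;
    // w from torque
    double iq7 = iq5 * iq2;
    double c1 = 0.25 * (10.0 * e2 * e2 - 2.0 * r2 * r2 - 7.0 * e2 * r2) * iq7;
    double c2 = 0.75 * (2.0 * r2 + 7.0 * e2) * iq7;
    w += T * c1 + r * (c2 * dot(T, r));
  }
}

// Image-system contribution for a no-slip wall at z = 0 (source at height
// src.z > 0).  Exactly cancels the free-space field on the wall.
inline void add_wall_image_field(const Vec3& target, const Vec3& src, double e,
                                 const Vec3& F, const Vec3& T,
                                 Vec3& u, Vec3& w, bool want_w) {
  double h = src.z;
  double d = std::sqrt(h * h + e * e);
  double uim[3], cim[3];
  wall_image_uc(target.x - src.x, target.y - src.y, target.z + d,
                h, e, d, F.x, F.y, F.z, T.x, T.y, T.z, uim, cim);
  u += Vec3(uim[0], uim[1], uim[2]);
  if (want_w) w += Vec3(0.5 * cim[0], 0.5 * cim[1], 0.5 * cim[2]);
}

inline void add_field(const Vec3& target, const Vec3& src, double e,
                      const Vec3& F, const Vec3& T,
                      Vec3& u, Vec3& w, bool want_w, bool wall) {
  add_free_field(target, src, e, F, T, u, w, want_w);
  if (wall) add_wall_image_field(target, src, e, F, T, u, w, want_w);
}

#endif
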