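#ifndef LOPHO_UTIL_H
#define LOPHO_UTIL_H

#include <cmath>

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x+o.x, y+o.y, z+o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x-o.x, y-o.y, z-o.z); }
  Vec3 operator*(double s) const { return Vec3(x*s, y*s, z*s); }
  Vec3 operator-() const { return Vec3(-x, -y, -z); }
  Vec3& operator+=(const Vec3& o) { x+=o.x; y+=o.y; z+=o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x-=o.x; y-=o.y; z-=o.z; return *this; }
};

inline Vec3 operator*(double s, const Vec3& v) { return v * s; }
inline double dot(const Vec3& a, const Vec3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
inline double norm(const Vec3& v) { return std::sqrt(dot(v, v)); }

// Rotate v by angle theta about unit axis n (Rodrigues).
inline Vec3 rotate_about(const Vec3& v, const Vec3& n, double theta) {
  double c = std::cos(theta), s = std::sin(theta);
  return v * c + cross(n, v) * s + n * (dot(n, v) * (1.0 - c));
}

// 3x3 rotation stored column-major as arrays of Vec3 columns elsewhere; here
// small helpers for axis-angle of a rotation matrix given by its action.

#endif
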