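#include <cmath>
using std::sqrt;
using std::pow;
// generated by scratch/gen_kernels.py -- wall image fields
// u_img and curl(u_img), both times (8 pi mu); r = target - image point
static inline void wall_image_uc(double rx, double ry, double rz,
    double h, double e, double d,
    double Fx, double Fy, double Fz,
    double Tx, double Ty, double Tz,
    double* u, double* c) {
  const double x0 = ((rx)*(rx));
  const double x1 = ((ry)*(ry));
  const double x2 = ((rz)*(rz));
  const double x3 = x0 + x1 + x2;
  const double x4 = (1.0/sqrt(x3));
  const double x5 = 1.0/x3;
  const double x6 = 1.0/d;
  const double x7 = ((e)*(e));
  const double x8 = x6*x7;
  const double x9 = rz*x5;
  const double x10 = 3*x9;
  const double x11 = x10*x8;
  const double x12 = x11 + 2;
  const double x13 = d + h;
  const double x14 = h*x13;
  const double x15 = x14*x5;
  const double x16 = 3*x15;
  const double x17 = x14*x6;
  const double x18 = x10*x17;
  const double x19 = x16 - x18 + 1;
  const double x20 = Fy*rx;
  const double x21 = ry*x5;
  const double x22 = x20*x21;
  const double x23 = 3*x13;
  const double x24 = x23*x9;
  const double x25 = x2*x5;
  const double x26 = 3*x25;
  const double x27 = x26 - 1;
  const double x28 = x13*x27;
  const double x29 = -d*x24 + rz + x28;
  const double x30 = Fz*rx;
  const double x31 = ((d)*(d));
  const double x32 = 1.0/x31;
  const double x33 = x32*x7;
  const double x34 = x13*x33;
  const double x35 = (1.0/((d)*(d)*(d)));
  const double x36 = 2*x31 + x7;
  const double x37 = h*x35*x36;
  const double x38 = x37 + 2;
  const double x39 = rz*x38;
  const double x40 = d*x38;
  const double x41 = 5*x13;
  const double x42 = x41*x8*x9;
  const double x43 = 5*x25;
  const double x44 = x43 - 1;
  const double x45 = x34*x44;
  const double x46 = x34 + x39 - x40 - x42 + x45;
  const double x47 = Tx*rx;
  const double x48 = (1.0/((x3)*(x3)));
  const double x49 = (3.0/2.0)*ry*x48;
  const double x50 = x0*x5;
  const double x51 = 3*x50;
  const double x52 = x51 - 1;
  const double x53 = x51 + 1;
  const double x54 = x17*x9;
  const double x55 = x6*(2*x14 + x7);
  const double x56 = x55*x9;
  const double x57 = x56 + 1;
  const double x58 = -x34 + x40;
  const double x59 = -x26;
  const double x60 = x59 + 1;
  const double x61 = x2*x48;
  const double x62 = 15*x61;
  const double x63 = x0*x62;
  const double x64 = -x51 + x63;
  const double x65 = x60 + x64;
  const double x66 = 5*x50;
  const double x67 = x66 - 1;
  const double x68 = rz*x37;
  const double x69 = h*x33;
  const double x70 = x27*x69 + x68;
  const double x71 = (1.0/2.0)*Tz;
  const double x72 = rx*x5;
  const double x73 = Fx*ry;
  const double x74 = x72*x73;
  const double x75 = x1*x5;
  const double x76 = 3*x75;
  const double x77 = x76 - 1;
  const double x78 = x76 + 1;
  const double x79 = x1*x62;
  const double x80 = -x76 + x79;
  const double x81 = x60 + x80;
  const double x82 = 5*x75;
  const double x83 = x82 - 1;
  const double x84 = rz*x16;
  const double x85 = rz - x55;
  const double x86 = x84 + x85;
  const double x87 = x5*(-x17*x27 + x86);
  const double x88 = x5*x8;
  const double x89 = x23*x88;
  const double x90 = x26 + 1;
  const double x91 = x58*x9;
  const double x92 = x10*x69;
  const double x93 = x37 + 3*x91 + x92;
  const double x94 = -x10*x45 - x38*x90 + x93;
  const double x95 = (1.0/2.0)*Ty;
  const double x96 = (1.0/(x3*sqrt(x3)));
  const double x97 = (3.0/2.0)*x72;
  const double x98 = Tz*(2*rz + x43*x8 - x8);
  const double x99 = 5*rz*x15;
  const double x100 = rz - x17*x43 + x17 + x99;
  const double x101 = -x17*x44 + x85 + x99;
  const double x102 = d*x23*x5;
  const double x103 = -x102*x44 + x24*x44 + x90;
  const double x104 = x43 - 3;
  const double x105 = -d*x13*x62 + x102 + x104*x24 + x27;
  const double x106 = -rz*x76;
  const double x107 = -rz - x26*x55 + x55;
  const double x108 = 15*x48;
  const double x109 = x1*x108;
  const double x110 = x109*x14;
  const double x111 = 5*x91;
  const double x112 = x41*x88;
  const double x113 = 35*x61;
  const double x114 = x13*x8;
  const double x115 = 7*x25;
  const double x116 = 5*x9;
  const double x117 = x116*x34;
  const double x118 = x111 - x112 + x113*x114 - x117*(x115 - 3) - x38*x43 + x38;
  const double x119 = (3.0/2.0)*x21;
  const double x120 = Ty*x119;
  const double x121 = x115 - 1;
  const double x122 = x111 + x116*x69 - x117*x121 + x37 - x38*(x43 + 1);
  const double x123 = x58*x83;
  const double x124 = -x43;
  const double x125 = x1*x113 + x124;
  const double x126 = x125 - x82 + 1;
  const double x127 = -x126*x89;
  const double x128 = x10*x34;
  const double x129 = x104*x92 + x26*x37 - x37;
  const double x130 = x126*x34;
  const double x131 = -rz*x51;
  const double x132 = x0*x108;
  const double x133 = x132*x14;
  const double x134 = x0*x113 + x124;
  const double x135 = x134 - x66 + 1;
  const double x136 = -3*x13*x135*x5*x6*x7;
  const double x137 = x135*x34;
  const double x138 = rz*x8;
  const double x139 = -x11 - 2;
  const double x140 = rz*x17;
  const double x141 = -x16 + x18;
  const double x142 = 3*x56;
  const double x143 = x44*x69 + x68;
  const double x144 = Tx*x97;
  const double x145 = -x39 + x42 + x58;
  u[0] = x4*(-Fx*(x15*x52 + x50 - x53*x54 + x57) + (1.0/2.0)*Ty*x5*(-x24*x67*x8 + x34*x65 + x39*x52 - x52*x58 + x70) + (1.0/2.0)*Tz*ry*x12*x5 - x19*x22 - x29*x30*x5 - x46*x47*x49);
  u[1] = x4*(-Fy*(x15*x77 - x54*x78 + x57 + x75) - Fz*ry*x29*x5 + (1.0/2.0)*Tx*x5*(3*rz*x13*x5*x6*x7*x83 - x34*x81 - x39*x77 + x58*x77 - x70) + Ty*rx*x46*x49 - x12*x71*x72 - x19*x74);
  u[2] = x4*(-Fx*rx*x87 - Fy*ry*x87 + Fz*(d*x13*x27*x5 - x25 - x28*x9 - 1) + (1.0/2.0)*Tx*ry*x5*(x44*x89 + x94) - rx*x5*x95*(x44*x89 + x94));
  c[0] = x96*(3*Fx*rx*ry*x101*x5 + Fy*(x106 + x107 + x17*(x27 + x80) - x83*x84) - Fy*(-rz*x110 + x106 + x17*x81 + x55*x76 + x86) + Fz*ry*x103 - Fz*ry*x105 - 1.0/2.0*Tx*(-x10*x123 + x127 + x128*(x125 - 15*x75 + 3) + x129 + x38*x81) + (1.0/2.0)*Tx*(-rz*x109*x58 - rz*x109*x69 + x10*x130 + x127 - x37*x76 + x38*(x59 + x77 + x79) + x93) + (3.0/2.0)*Ty*rx*ry*x5*(x112*x121 + x122) - rx*x118*x120 - 3*x100*x74 - x97*x98);
  c[1] = x96*(-Fx*(x107 + x131 + x17*(x27 + x64) - x67*x84) + Fx*(-rz*x133 + x131 + x17*x65 + x51*x55 + x86) + 3*Fy*rx*ry*x100*x5 + Fz*rx*x105 + (3.0/2.0)*Tx*rx*ry*x5*(x112*x121 + x122) + (1.0/2.0)*Ty*(3*rz*x5*x58*x67 - x128*(x134 - 15*x50 + 3) - x129 - x136 - x38*x65) - 3*x101*x22 - x103*x30 - x118*x119*x47 - x119*x98 - x95*(15*h*rz*x0*x32*x48*x7 + 3*h*x0*x35*x36*x5 + 15*rz*x0*x48*x58 - x10*x137 - x136 - x38*(x52 + x59 + x63) - x93));
  c[2] = x96*(x120*(35*rz*x0*x13*x48*x6*x7 + 5*x0*x5*x58 - x137 - x145 - x39*x66) - x120*(5*rz*x13*x5*x6*x7*(7*x50 - 1) - x137 - x143 - x39*x67 + x58*x67) + x144*(-x123 + x130 + x143 + x39*x83 - x42*(7*x75 - 1)) - x144*(-35*rz*x1*x114*x48 + x130 + x145 + x39*x82 - x58*x82) + x20*(x142 + x16*x83 - x18*(x82 + 1) + x78) - x20*(-x109*x140 + x110 + x141 + x77) + x71*(x109*x138 + x139 + 6*x75) + x71*(x132*x138 + x139 + 6*x50) - x73*(x142 + x16*x67 - x18*(x66 + 1) + x53) + x73*(-x132*x140 + x133 + x141 + x52));
}
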