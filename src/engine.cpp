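#include <Rcpp.h>
#include <vector>
#include "fields.h"
#include "rod_core.h"
#include "rigid_core.h"

using namespace Rcpp;

// Full explicit time stepper for the coupled flagellum / cell body / Stokes
// fluid system.  Marker updates follow the slip-velocity form
//   dX/dt  = u(X)  - (1/alpha1) [f + steric + wall]      (rod markers)
//   dXb/dt = u(Xb) - (1/alpha2) [Fb - steric - wall]     (body markers)
//   dDj/dt = (w - (1/beta) n3 D3) x Dj                   (triads, exact map)
// followed by the quasi-static rigid body solve.  The force the immersed
// cell exerts on the fluid is the negative of each marker's slip bracket,
// so the assembled source system is force-free up to the motor/clamp pairs
// which cancel between rod and body by construction.

struct Schedule {
  std::vector<double> t0, t1, tau;
  double ramp = 0.0;   // linear blend-in time at segment starts (s)
  int cached = 0;
  double value(int i, double t) {
    if (ramp <= 0.0) return tau[i];
    double dt = t - t0[i];
    if (dt >= ramp) return tau[i];
    double prev = (i > 0) ? tau[i-1] : 0.0;   // motor starts from rest
    return prev + (tau[i] - prev) * (dt / ramp);
  }
  double at(double t) {
    int n = t0.size();
    if (cached >= n) cached = 0;
    for (int k = 0; k < n; ++k) {
      int i = (cached + k) % n;
      if (t >= t0[i] && t < t1[i]) { cached = i; return value(i, t); }
    }
    // allow the exact right endpoint of the last segment (no extrapolation)
    if (std::fabs(t - t1[n-1]) <= 1e-12) return tau[n-1];
    return NA_REAL;
  }
};

static Quat quat_from_R(const double* R) {
  Vec3 c1(R[0], R[1], R[2]), c2(R[3], R[4], R[5]), c3(R[6], R[7], R[8]);
  Vec3 e1(1,0,0), e2(0,1,0), e3(0,0,1);
  return quat_between_triads(e1, e2, e3, c1, c2, c3);
}

static double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// [[Rcpp::export]]
List cpp_run(List pack, int nsteps, int record_every, int snap_every) {
  // ---- unpack ----
  NumericMatrix Xm = pack["X"], D1m = pack["D1"], D2m = pack["D2"], D3m = pack["D3"];
  NumericMatrix amodm = pack["amod"], bmodm = pack["bmod"], Omm = pack["Om"], Gamm = pack["Gam"];
  NumericVector srefv = pack["sref"];
  NumericMatrix Zm = pack["Z"], Xbm = pack["Xb"], Rotm = pack["Rot"];
  NumericVector Tv = pack["T"], Erefv = pack["Eref"], ref1v = pack["ref1"], ref2v = pack["ref2"];
  double ds = pack["ds"], epsf = pack["eps_f"], epsb = pack["eps_b"];
  double inva1 = pack["inv_alpha1"], inva2 = pack["inv_alpha2"], invbeta = pack["inv_beta"];
  double K = pack["K"], Km = pack["K_m"], Kc = pack["K_c"];
  double Crep = pack["C_rep"], Drep = pack["D_rep"], Lp = pack["L_prime"];
  double cw = pack["c_w"], Dw = pack["D_w"];
  bool wall = pack["wall"], wall_spread = pack["wall_spread"];
  bool self_rotlet = pack.containsElementNamed("self_rotlet") ?
      as<bool>(pack["self_rotlet"]) : true;
  double mu = pack["mu"], dt = pack["dt"], t0 = pack["t0"];
  int motor_i = as<int>(pack["motor_index"]) - 1;  // 0-based
  double rigid_tol = pack["rigid_tol"];
  double theta_c = pack.containsElementNamed("theta_c") ? as<double>(pack["theta_c"]) : M_PI;
  int rigid_maxit = as<int>(pack["rigid_maxit"]);
  double phase_motor = pack["phase_motor"], roll_body = pack["roll_body"];
  List sched = pack["schedule"];
  Schedule S;
  S.t0 = as<std::vector<double> >(sched["t_start"]);
  S.t1 = as<std::vector<double> >(sched["t_end"]);
  S.tau = as<std::vector<double> >(sched["tau"]);
  S.ramp = sched.containsElementNamed("ramp") ? as<double>(sched["ramp"]) : 0.0;

  int nf = Xm.nrow(), nb = Zm.nrow(), nseg = nf - 1;
  std::vector<Vec3> X(nf), D1(nf), D2(nf), D3(nf), Z(nb), Xb(nb);
  for (int j = 0; j < nf; ++j) {
    X[j] = Vec3(Xm(j,0), Xm(j,1), Xm(j,2));
    D1[j] = Vec3(D1m(j,0), D1m(j,1), D1m(j,2));
    D2[j] = Vec3(D2m(j,0), D2m(j,1), D2m(j,2));
    D3[j] = Vec3(D3m(j,0), D3m(j,1), D3m(j,2));
  }
  for (int i = 0; i < nb; ++i) {
    Z[i] = Vec3(Zm(i,0), Zm(i,1), Zm(i,2));
    Xb[i] = Vec3(Xbm(i,0), Xbm(i,1), Xbm(i,2));
  }
  std::vector<double> amod(nseg*3), bmod(nseg*3), Om(nseg*3), Gam(nseg*3), sref(nf);
  for (int j = 0; j < nseg; ++j)
    for (int k = 0; k < 3; ++k) {
      amod[3*j+k] = amodm(j,k); bmod[3*j+k] = bmodm(j,k);
      Om[3*j+k] = Omm(j,k); Gam[3*j+k] = Gamm(j,k);
    }
  for (int j = 0; j < nf; ++j) sref[j] = srefv[j];
  Vec3 T(Tv[0], Tv[1], Tv[2]);
  double R[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R[3*c + r] = Rotm(r, c);
  Vec3 Eref(Erefv[0], Erefv[1], Erefv[2]);
  Vec3 ref1(ref1v[0], ref1v[1], ref1v[2]), ref2(ref2v[0], ref2v[1], ref2v[2]);

  RodWork rw; rw.resize(nf);
  // per-segment quaternion continuity buffer (joint-angle unwrapping)
  std::vector<Quat> qc(nseg);
  for (int j = 0; j < nseg; ++j) { qc[j].w = 1; qc[j].x = qc[j].y = qc[j].z = 0; }
  if (pack.containsElementNamed("qseg")) {
    NumericMatrix qm = pack["qseg"];
    if (qm.nrow() == nseg) for (int j = 0; j < nseg; ++j) {
      qc[j].w = qm(j,0); qc[j].x = qm(j,1); qc[j].y = qm(j,2); qc[j].z = qm(j,3);
    }
  }
  std::vector<Vec3> srod(nf), wrod(nf), wbody(nb), Fb(nb), brod(nf), bbody(nb);
  std::vector<Vec3> u_all(nf + nb), w_rod(nf);
  std::vector<Vec3> srcF(nf + nb), srcT(nf + nb), srcP(nf + nb);
  std::vector<double> srcE(nf + nb);

  int nrec = nsteps / record_every + 1;
  const int NCOL = 20;
  NumericMatrix rec(nrec, NCOL);
  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_t;
  int irec = 0, status = 0, failstep = -1;
  std::string failmsg = "";
  Vec3 Tprev = T;
  double prev_phi = 0.0;
  bool have_prev_phi = false;

  for (int step = 0; step <= nsteps; ++step) {
    double t = t0 + step * dt;
    // the final step may overshoot the schedule end by less than one dt
    // when the duration is not a step multiple; clamp the lookup time
    double tlook = t;
    double tend = S.t1.back();
    if (t > tend && t - tend <= dt) tlook = tend;
    double tau = S.at(tlook);
    if (ISNAN(tau)) { status = 4; failstep = step; failmsg = "time outside motor schedule"; break; }

    // body pose derived quantities
    Vec3 E; mat3_vec(R, Eref, E);
    Vec3 e1b, e2b; mat3_vec(R, ref1, e1b); mat3_vec(R, ref2, e2b);
    Vec3 RZm; mat3_vec(R, Z[motor_i], RZm);
    Vec3 Yb1 = T + RZm;

    // motor phase tracking (D1 at the base, measured in the body frame)
    double phi = std::atan2(dot(D1[0], e2b), dot(D1[0], e1b));
    if (have_prev_phi) phase_motor += wrap_pi(phi - prev_phi);
    prev_phi = phi; have_prev_phi = true;

    // ---- elastic forces ----
    rod_measure(nf, X.data(), D1.data(), D2.data(), D3.data(), ds, rw, theta_c, qc.data());
    rod_resultants(nf, amod.data(), bmod.data(), Om.data(), Gam.data(), rw);
    Vec3 Nghost = E * (-tau);
    rod_densities(nf, X.data(), ds, Vec3(), Nghost, rw);

    // ---- motor constraints and body loads ----
    Vec3 fb_load, nb_load;
    // clamp: force on rod marker 0 is Kc*(Yb1 - X0); holding convention in f
    Vec3 Fc = (Yb1 - X[0]) * Kc;
    rw.f[0] -= Fc * (1.0 / ds);
    fb_load -= Fc;
    nb_load -= cross(RZm, Fc);
    // alignment feedback moment: ntil is the restoring torque ON the rod;
    // in the holding-torque convention of n it enters negated, so the fluid
    // rotlet source (-n ds) carries +ntil and reorients the proximal triad.
    Vec3 ntil = cross(E, D3[0]) * (-Km);
    rw.n[0] -= ntil * (1.0 / ds);
    nb_load -= ntil;
    // motor ghost torque reaction on the body
    nb_load += Nghost;

    // ---- steric (flagellum-body) ----
    double minster = 1e300;
    for (int j = 0; j < nf; ++j) srod[j] = Vec3();
    std::vector<Vec3> sbody(nb, Vec3());
    for (int j = 0; j < nf; ++j) {
      if (sref[j] < Lp) continue;
      for (int i = 0; i < nb; ++i) {
        Vec3 dv = X[j] - Xb[i];
        double dist = norm(dv);
        if (dist < minster) minster = dist;
        if (dist >= Drep) continue;
        if (dist < 1e-12) { status = 5; failstep = step; failmsg = "coincident steric pair"; break; }
        Vec3 pF = dv * (Crep * (1.0 - dist / Drep) / dist);  // force on rod, per unit s
        srod[j] += pF;
        sbody[i] -= pF * ds;     // point-force reaction on the body marker
      }
      if (status) break;
    }
    if (status) break;

    // ---- wall repulsion (point forces) ----
    if (wall) {
      for (int j = 0; j < nf; ++j) {
        double z = X[j].z;
        wrod[j] = (z < Dw) ? Vec3(0, 0, cw * (1.0 - z / Dw)) : Vec3();
        if (z <= 0) { status = 3; failstep = step; failmsg = "rod marker reached the wall"; break; }
      }
      if (!status) for (int i = 0; i < nb; ++i) {
        double z = Xb[i].z;
        wbody[i] = (z < Dw) ? Vec3(0, 0, cw * (1.0 - z / Dw)) : Vec3();
        if (z <= 0) { status = 3; failstep = step; failmsg = "body marker reached the wall"; break; }
      }
      if (status) break;
    }

    // ---- penalty forces, brackets, fluid sources ----
    double penmax = 0.0;
    for (int i = 0; i < nb; ++i) {
      Vec3 RZ; mat3_vec(R, Z[i], RZ);
      Vec3 Yb = T + RZ;
      Fb[i] = (Xb[i] - Yb) * K;
      double g = norm(Xb[i] - Yb);
      if (g > penmax) penmax = g;
    }
    for (int j = 0; j < nf; ++j) {
      brod[j] = rw.f[j] - srod[j];                 // density bracket
      if (wall) brod[j] -= wrod[j] * (1.0 / ds);
      srcP[j] = X[j];
      srcF[j] = brod[j] * (-ds);
      if (wall && !wall_spread) srcF[j] -= wrod[j];
      srcT[j] = rw.n[j] * (-ds);
      srcE[j] = epsf;
    }
    for (int i = 0; i < nb; ++i) {
      bbody[i] = Fb[i] - sbody[i];                 // point-force bracket
      if (wall) bbody[i] -= wbody[i];
      srcP[nf + i] = Xb[i];
      srcF[nf + i] = -bbody[i];
      if (wall && !wall_spread) srcF[nf + i] -= wbody[i];
      srcT[nf + i] = Vec3();
      srcE[nf + i] = epsb;
    }

    // ---- record (uses source sums for diagnostics) ----
    if (step % record_every == 0 && irec < nrec) {
      Vec3 netF, netT;
      for (int k = 0; k < nf + nb; ++k) {
        netF += srcF[k];
        netT += cross(srcP[k] - T, srcF[k]) + srcT[k];
      }
      Vec3 dT = (step == 0) ? Vec3() : (T - Tprev) * (1.0 / dt);
      double Vf = -dot(dT, E);
      Quat q = quat_from_R(R);
      rec(irec, 0) = t;
      rec(irec, 1) = T.x; rec(irec, 2) = T.y; rec(irec, 3) = T.z;
      rec(irec, 4) = q.w; rec(irec, 5) = q.x; rec(irec, 6) = q.y; rec(irec, 7) = q.z;
      rec(irec, 8) = E.x; rec(irec, 9) = E.y; rec(irec, 10) = E.z;
      rec(irec, 11) = Vf;
      rec(irec, 12) = phase_motor;
      rec(irec, 13) = roll_body;
      rec(irec, 14) = T.z;
      rec(irec, 15) = norm(netF);
      rec(irec, 16) = norm(netT);
      rec(irec, 17) = penmax;
      rec(irec, 18) = norm(X[0] - Yb1);
      rec(irec, 19) = (minster > 1e299) ? NA_REAL : minster;
      if (snap_every > 0 && irec % snap_every == 0) {
        NumericMatrix sn(nf, 3);
        for (int j = 0; j < nf; ++j) { sn(j,0) = X[j].x; sn(j,1) = X[j].y; sn(j,2) = X[j].z; }
        snaps.push_back(sn);
        snap_t.push_back(t);
      }
      ++irec;
    }
    if (step == nsteps) break;

    // ---- fluid evaluation ----
    int ns = nf + nb;
    for (int jt = 0; jt < nf + nb; ++jt) {
      Vec3 x = (jt < nf) ? X[jt] : Xb[jt - nf];
      Vec3 u, w;
      bool want_w = jt < nf;
      for (int js = 0; js < ns; ++js) {
        // optionally exclude a marker's own rotlet from the angular
        // velocity that rotates its triad: the roll resistance of the
        // filament is then set by beta instead of the blob self-mobility
        Vec3 Tq = (!self_rotlet && js == jt) ? Vec3() : srcT[js];
        add_field(x, srcP[js], srcE[js], srcF[js], Tq, u, w, want_w, wall);
      }
      double sc = 1.0 / (8.0 * M_PI * mu);
      u_all[jt] = u * sc;
      if (want_w) w_rod[jt] = w * sc;
    }

    // ---- marker updates ----
    Tprev = T;
    double maxdisp = 0.0;
    for (int j = 0; j < nf; ++j) {
      Vec3 v = u_all[j] - brod[j] * inva1;
      Vec3 dx = v * dt;
      double dn = norm(dx);
      if (dn > maxdisp) maxdisp = dn;
      X[j] += dx;
      Vec3 wt = w_rod[j] - D3[j] * (invbeta * dot(rw.n[j], D3[j]));
      double th = norm(wt) * dt;
      if (th > 1e-14) {
        Vec3 ax = wt * (1.0 / (norm(wt)));
        D1[j] = rotate_about(D1[j], ax, th);
        D2[j] = rotate_about(D2[j], ax, th);
        D3[j] = rotate_about(D3[j], ax, th);
      }
    }
    for (int i = 0; i < nb; ++i) {
      Vec3 v = u_all[nf + i] - bbody[i] * inva2;
      Vec3 dx = v * dt;
      double dn = norm(dx);
      if (dn > maxdisp) maxdisp = dn;
      Xb[i] += dx;
    }
    if (!std::isfinite(maxdisp) || maxdisp > 0.5 * ds) {
      status = 1; failstep = step; failmsg = "marker displacement blow-up";
      break;
    }

    // ---- rigid solve ----
    double Rold[9];
    for (int k = 0; k < 9; ++k) Rold[k] = R[k];
    int it = rigid_solve_core(nb, Xb.data(), Z.data(), K, fb_load, nb_load,
                              T, R, rigid_tol, rigid_maxit);
    if (it < 0) { status = 2; failstep = step; failmsg = "rigid body solve did not converge"; break; }
    // body roll about E from the incremental rotation
    {
      Vec3 c1o(Rold[0], Rold[1], Rold[2]), c2o(Rold[3], Rold[4], Rold[5]), c3o(Rold[6], Rold[7], Rold[8]);
      Vec3 c1n(R[0], R[1], R[2]), c2n(R[3], R[4], R[5]), c3n(R[6], R[7], R[8]);
      Quat qd = quat_between_triads(c1o, c2o, c3o, c1n, c2n, c3n);
      double sgn = qd.w >= 0 ? 1.0 : -1.0;
      Vec3 dang = Vec3(qd.x, qd.y, qd.z) * (2.0 * sgn);
      Vec3 Enew; mat3_vec(R, Eref, Enew);
      roll_body += dot(dang, Enew);
    }
  }

  // pack final state
  NumericMatrix Xo(nf,3), D1o(nf,3), D2o(nf,3), D3o(nf,3), Xbo(nb,3), Ro(3,3);
  for (int j = 0; j < nf; ++j) {
    Xo(j,0)=X[j].x; Xo(j,1)=X[j].y; Xo(j,2)=X[j].z;
    D1o(j,0)=D1[j].x; D1o(j,1)=D1[j].y; D1o(j,2)=D1[j].z;
    D2o(j,0)=D2[j].x; D2o(j,1)=D2[j].y; D2o(j,2)=D2[j].z;
    D3o(j,0)=D3[j].x; D3o(j,1)=D3[j].y; D3o(j,2)=D3[j].z;
  }
  for (int i = 0; i < nb; ++i) { Xbo(i,0)=Xb[i].x; Xbo(i,1)=Xb[i].y; Xbo(i,2)=Xb[i].z; }
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) Ro(r,c) = R[3*c + r];
  if (irec < nrec) rec = rec(Range(0, std::max(irec - 1, 0)), _);
  NumericMatrix qso(nseg, 4);
  for (int j = 0; j < nseg; ++j) {
    qso(j,0) = qc[j].w; qso(j,1) = qc[j].x; qso(j,2) = qc[j].y; qso(j,3) = qc[j].z;
  }
  List snl(snaps.size());
  for (size_t k = 0; k < snaps.size(); ++k) snl[k] = snaps[k];
  return List::create(
    _["records"] = rec, _["snapshots"] = snl,
    _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["X"] = Xo, _["D1"] = D1o, _["D2"] = D2o, _["D3"] = D3o,
    _["Xb"] = Xbo, _["qseg"] = qso,
    _["T"] = NumericVector::create(T.x, T.y, T.z), _["Rot"] = Ro,
    _["phase_motor"] = phase_motor, _["roll_body"] = roll_body,
    _["status"] = status, _["fail_step"] = failstep, _["fail_message"] = failmsg);
}
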