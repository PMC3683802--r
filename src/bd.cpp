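// Overdamped (Brownian) dynamics for mixed rigid-body + flexible-bead
// systems. Rigid bodies translate under their net force and rotate under
// their net torque with isotropic scalar mobilities; fluctuation-dissipation
// holds at the set temperature for every degree of freedom.
#include <Rcpp.h>
#include <random>
#include "sys.h"
using namespace Rcpp;

struct Quat {
  double w, x, y, z;
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
  void rot(const double v[3], double out[3]) const {
    // rotation matrix applied to v
    double r00 = 1 - 2 * (y * y + z * z), r01 = 2 * (x * y - w * z), r02 = 2 * (x * z + w * y);
    double r10 = 2 * (x * y + w * z), r11 = 1 - 2 * (x * x + z * z), r12 = 2 * (y * z - w * x);
    double r20 = 2 * (x * z - w * y), r21 = 2 * (y * z + w * x), r22 = 1 - 2 * (x * x + y * y);
    out[0] = r00 * v[0] + r01 * v[1] + r02 * v[2];
    out[1] = r10 * v[0] + r11 * v[1] + r12 * v[2];
    out[2] = r20 * v[0] + r21 * v[1] + r22 * v[2];
  }
};

static Quat quat_mul(const Quat &a, const Quat &b) {
  Quat q;
  q.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  q.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  q.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  q.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return q;
}

static Quat quat_from_rotvec(double rx, double ry, double rz) {
  double phi = std::sqrt(rx * rx + ry * ry + rz * rz);
  Quat q{1, 0, 0, 0};
  if (phi < 1e-14) return q;
  double s = std::sin(0.5 * phi) / phi;
  q.w = std::cos(0.5 * phi); q.x = rx * s; q.y = ry * s; q.z = rz * s;
  return q;
}

// Verlet pair list over both interaction groups (rigid-body long-range
// types all-pairs; bead types via a cell grid), rebuilt when any bead has
// moved more than half the skin since the last build.
struct PairList {
  std::vector<int> pi, pj;
  size_t na = 0;           // first na entries use rc_a, the rest rc_b
  double rc_a = 0, rc_b = 0;
  std::vector<double> x0, y0, z0;

  void build(const Sys &s, const FF &ff, double skin) {
    pi.clear(); pj.clear();
    std::vector<int> ga, gb;
    for (int i = 0; i < s.N; ++i) {
      if (s.type[i] <= BOT) ga.push_back(i);
      else if (s.type[i] != INERT) gb.push_back(i);
    }
    rc_a = std::max(ff.rcut_morse, std::max(ff.sigma_t, ff.sigma_b));
    rc_b = std::max(std::max(ff.sigma_xp, ff.sigma_xa), ff.rc_dh);
    auto admit = [&](int i, int j, double rc) {
      if (s.body[i] > 0 && s.body[i] == s.body[j]) return;
      double dx = min_image(s.x[i] - s.x[j], s.box);
      double dy = min_image(s.y[i] - s.y[j], s.box);
      double dz = min_image(s.z[i] - s.z[j], s.box);
      if (dx * dx + dy * dy + dz * dz >= rc * rc) return;
      if (s.excluded(i, j)) return;
      pi.push_back(i); pj.push_back(j);
    };
    for (size_t a = 0; a < ga.size(); ++a)
      for (size_t b = a + 1; b < ga.size(); ++b)
        admit(ga[a], ga[b], rc_a + skin);
    na = pi.size();
    if (!gb.empty()) {
      if (s.box > 0 && s.box < 3 * (rc_b + skin)) {
        for (size_t a = 0; a < gb.size(); ++a)
          for (size_t b = a + 1; b < gb.size(); ++b)
            admit(gb[a], gb[b], rc_b + skin);
      } else {
        CellGrid g;
        g.build(s.x, s.y, s.z, &gb, s.N, rc_b + skin, s.box);
        for (int i : gb)
          g.for_neighbors(s.x[i], s.y[i], s.z[i], [&](int j) {
            if (j > i) admit(i, j, rc_b + skin);
          });
      }
    }
    x0 = s.x; y0 = s.y; z0 = s.z;
  }

  bool stale(const Sys &s, double skin) const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < s.N; ++i) {
      double dx = s.x[i] - x0[i], dy = s.y[i] - y0[i], dz = s.z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  void accumulate(const Sys &s, const FF &ff, EnergyAcc &acc,
                  std::vector<double> *fx, std::vector<double> *fy,
                  std::vector<double> *fz) const {
    double rc2_a = rc_a * rc_a, rc2_b = rc_b * rc_b;
    for (size_t k = 0; k < pi.size(); ++k) {
      int i = pi[k], j = pj[k];
      double rc2 = k < na ? rc2_a : rc2_b;
      double dx = min_image(s.x[i] - s.x[j], s.box);
      double dy = min_image(s.y[i] - s.y[j], s.box);
      double dz = min_image(s.z[i] - s.z[j], s.box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) r = 1e-12;
      double dudr; int bucket;
      bool cp_off = s.cp_off[i] || s.cp_off[j];
      double u = pair_energy(s.type[i], s.type[j], s.charge[i], s.charge[j],
                             r, ff, cp_off, &dudr, &bucket, &acc.ncap);
      if (bucket >= 0) acc.bucket[bucket] += u;
      if (fx && dudr != 0.0) {
        double fmag = -dudr / r;
        (*fx)[i] += fmag * dx; (*fy)[i] += fmag * dy; (*fz)[i] += fmag * dz;
        (*fx)[j] -= fmag * dx; (*fy)[j] -= fmag * dy; (*fz)[j] -= fmag * dz;
      }
    }
  }
};

// [[Rcpp::export]]
List cs_bd_run(List sys, List ff, double dt, double n_steps,
               double temperature, double gamma, int seed,
               double out_stride = 0, double skin = 1.0,
               IntegerVector fixed_bodies = IntegerVector(0)) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  long nsteps = (long)n_steps;
  long stride = out_stride > 0 ? (long)out_stride : nsteps;
  if (stride < 1) stride = 1;

  int nbody = 0;
  for (int i = 0; i < s.N; ++i) nbody = std::max(nbody, s.body[i]);
  std::vector<std::vector<int>> members(nbody + 1);
  for (int i = 0; i < s.N; ++i)
    if (s.body[i] > 0) members[s.body[i]].push_back(i);
  std::vector<bool> fixed(nbody + 1, false);
  for (int k = 0; k < fixed_bodies.size(); ++k)
    if (fixed_bodies[k] >= 1 && fixed_bodies[k] <= nbody)
      fixed[fixed_bodies[k]] = true;

  // body reference frames from the initial coordinates
  std::vector<double> cx(nbody + 1), cy(nbody + 1), cz(nbody + 1);
  std::vector<Quat> qs(nbody + 1, Quat{1, 0, 0, 0});
  std::vector<std::vector<double>> loc(nbody + 1);
  std::vector<double> gam_r(nbody + 1, 0.0);
  for (int b = 1; b <= nbody; ++b) {
    double mx = 0, my = 0, mz = 0;
    for (int i : members[b]) { mx += s.x[i]; my += s.y[i]; mz += s.z[i]; }
    int n = members[b].size();
    cx[b] = mx / n; cy[b] = my / n; cz[b] = mz / n;
    loc[b].resize(3 * n);
    for (int k = 0; k < n; ++k) {
      int i = members[b][k];
      double lx = s.x[i] - cx[b], ly = s.y[i] - cy[b], lz = s.z[i] - cz[b];
      loc[b][3 * k] = lx; loc[b][3 * k + 1] = ly; loc[b][3 * k + 2] = lz;
      gam_r[b] += gamma * (lx * lx + ly * ly + lz * lz);
    }
    if (gam_r[b] < 1e-12) gam_r[b] = gamma;  // point-like body
  }

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  std::vector<double> px = s.x, py = s.y, pz = s.z;  // last good frame
  List frames, frame_energies;
  std::vector<double> frame_steps;
  long ncap_total = 0;
  std::string status = "ok";
  double max_disp = 0.0;

  auto snapshot = [&](long step) {
    NumericMatrix P(s.N, 3);
    for (int i = 0; i < s.N; ++i) { P(i, 0) = s.x[i]; P(i, 1) = s.y[i]; P(i, 2) = s.z[i]; }
    EnergyAcc acc;
    accumulate_pairs(s, f, acc, nullptr, nullptr, nullptr, false);
    accumulate_bonded(s, f, acc, nullptr, nullptr, nullptr);
    frames.push_back(P);
    frame_energies.push_back(NumericVector::create(
      acc.bucket[0], acc.bucket[1], acc.bucket[2], acc.bucket[3],
      acc.bucket[4], acc.bucket[5]));
    frame_steps.push_back((double)step);
  };

  double trans_noise = std::sqrt(2.0 * temperature * dt / gamma);
  long done = 0;
  PairList plist;
  plist.build(s, f, skin);
  for (long step = 1; step <= nsteps; ++step) {
    if (plist.stale(s, skin)) plist.build(s, f, skin);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    EnergyAcc acc;
    plist.accumulate(s, f, acc, &fx, &fy, &fz);
    accumulate_bonded(s, f, acc, &fx, &fy, &fz);
    ncap_total += acc.ncap;

    bool bad = false;
    // free beads
    for (int i = 0; i < s.N; ++i) {
      if (s.body[i] > 0) continue;
      double ddx = fx[i] * dt / gamma + trans_noise * gauss(rng);
      double ddy = fy[i] * dt / gamma + trans_noise * gauss(rng);
      double ddz = fz[i] * dt / gamma + trans_noise * gauss(rng);
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (!std::isfinite(d2)) { bad = true; break; }
      if (d2 > 0.25 * skin * skin) {
        status = "displacement_overflow"; bad = true; break;
      }
      max_disp = std::max(max_disp, std::sqrt(d2));
      s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
    }
    // rigid bodies
    for (int b = 1; b <= nbody && !bad; ++b) {
      int n = members[b].size();
      if (fixed[b]) { for (int k = 0; k < 3 * 2; ++k) gauss(rng); continue; }
      double Fx = 0, Fy = 0, Fz = 0, Tx = 0, Ty = 0, Tz = 0;
      for (int i : members[b]) {
        Fx += fx[i]; Fy += fy[i]; Fz += fz[i];
        double rx = s.x[i] - cx[b], ry = s.y[i] - cy[b], rz = s.z[i] - cz[b];
        Tx += ry * fz[i] - rz * fy[i];
        Ty += rz * fx[i] - rx * fz[i];
        Tz += rx * fy[i] - ry * fx[i];
      }
      double gt = gamma * n;
      double tn = std::sqrt(2.0 * temperature * dt / gt);
      double ddx = Fx * dt / gt + tn * gauss(rng);
      double ddy = Fy * dt / gt + tn * gauss(rng);
      double ddz = Fz * dt / gt + tn * gauss(rng);
      double rn = std::sqrt(2.0 * temperature * dt / gam_r[b]);
      double wx = Tx * dt / gam_r[b] + rn * gauss(rng);
      double wy = Ty * dt / gam_r[b] + rn * gauss(rng);
      double wz = Tz * dt / gam_r[b] + rn * gauss(rng);
      if (!std::isfinite(ddx + ddy + ddz + wx + wy + wz)) { bad = true; break; }
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > 0.25 * skin * skin) {
        status = "displacement_overflow"; bad = true; break;
      }
      cx[b] += ddx; cy[b] += ddy; cz[b] += ddz;
      Quat dq = quat_from_rotvec(wx, wy, wz);
      qs[b] = quat_mul(dq, qs[b]);
      qs[b].normalize();
      for (int k = 0; k < n; ++k) {
        int i = members[b][k];
        double v[3] = {loc[b][3 * k], loc[b][3 * k + 1], loc[b][3 * k + 2]}, o[3];
        qs[b].rot(v, o);
        s.x[i] = cx[b] + o[0]; s.y[i] = cy[b] + o[1]; s.z[i] = cz[b] + o[2];
      }
    }
    if (bad) {
      if (status == "ok") status = "nan_abort";
      s.x = px; s.y = py; s.z = pz;
      break;
    }
    px = s.x; py = s.y; pz = s.z;
    done = step;
    if (step % stride == 0) snapshot(step);
  }
  if (frame_steps.empty() || frame_steps.back() != (double)done)
    snapshot(done);

  NumericMatrix P(s.N, 3);
  for (int i = 0; i < s.N; ++i) { P(i, 0) = s.x[i]; P(i, 1) = s.y[i]; P(i, 2) = s.z[i]; }
  return List::create(
    _["pos"] = P, _["frames"] = frames,
    _["frame_energies"] = frame_energies,
    _["frame_steps"] = NumericVector(frame_steps.begin(), frame_steps.end()),
    _["status"] = status, _["n_capped"] = (double)ncap_total,
    _["max_displacement"] = max_disp);
}
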