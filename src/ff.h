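// Pair potentials of the coarse-grained capsid/NA model and their forces.
// All energies in kBT, lengths in nm. Bead type codes must match the R side
// (R/system.R): 0 attractor, 1 top, 2 bottom, 3 excluder, 4 arm, 5 polymer,
// 6 inert.
#pragma once
#include <cmath>
#include <cstdint>

enum BeadType { ATTR = 0, TOP = 1, BOT = 2, EXCL = 3, ARM = 4, POLY = 5, INERT = 6 };

// energy buckets of the six-term decomposition
enum Bucket { B_CC = 0, B_CP = 1, B_CA = 2, B_PP = 3, B_PA = 4, B_AA = 5, B_NONE = -1 };

struct FF {
  double eps;          // subunit interaction scale (kBT)
  double sigma_t;      // Top-Top diameter (nm)
  double sigma_b;      // Bottom-Top diameter (nm)
  double r0;           // Morse minimum (nm)
  double rho;          // Morse width parameter
  double rcut_morse;   // Morse cutoff (nm)
  double sigma_p;      // polymer bead diameter (nm)
  double sigma_x;      // excluder diameter (nm)
  double sigma_a;      // ARM bead diameter (nm)
  double lambda_D;     // Debye length (nm)
  double l_b;          // Bjerrum length (nm)
  double cap_frac;     // force-cap onset for the L term, fraction of sigma
  // derived
  double sigma_xp, sigma_xa, sigma_ap;
  double ron, rc_dh;   // switching-on and cutoff radii of the DH term
};

inline void ff_derive(FF &ff) {
  ff.sigma_xp = 0.5 * (ff.sigma_x + ff.sigma_p);
  ff.sigma_xa = 0.5 * (ff.sigma_x + ff.sigma_a);
  ff.sigma_ap = 0.5 * (ff.sigma_a + ff.sigma_p);
  ff.ron = 2.0 * ff.lambda_D;
  ff.rc_dh = 3.0 * ff.lambda_D;
}

// Repulsive LJ component shifted to zero at sigma, with a linear cap below
// cap_frac*sigma to keep integrators stable against rare deep overlaps.
inline double u_rep_lj(double x, double sigma, double cap_frac,
                       double *dudr, long *ncap) {
  if (x >= sigma) { *dudr = 0.0; return 0.0; }
  double xc = cap_frac * sigma;
  if (x < xc) {
    if (ncap) ++*ncap;
    double s6 = sigma / xc; s6 = s6 * s6 * s6; s6 = s6 * s6;
    double u_c = s6 * s6 - 1.0;
    double f_c = 12.0 * s6 * s6 / xc;  // -dU/dx at xc (repulsive, positive)
    *dudr = -f_c;
    return u_c + f_c * (xc - x);
  }
  double s6 = sigma / x; s6 = s6 * s6 * s6; s6 = s6 * s6;
  double u = s6 * s6 - 1.0;
  *dudr = -12.0 * s6 * s6 / x;
  return u;
}

// Morse potential (dimensionless; scale by eps at the call site)
inline double u_morse(double x, double r0, double rho, double rcut,
                      double *dudr) {
  if (x >= rcut) { *dudr = 0.0; return 0.0; }
  double m = std::exp(rho * (1.0 - x / r0));
  *dudr = -2.0 * (rho / r0) * (m - 1.0) * m;
  return (m - 2.0) * m;
}

// Debye-Hueckel with finite-ion-size prefactor, XPLOR-switched to zero over
// [2 lambda_D, 3 lambda_D].
inline double u_dh(double r, double q1q2, double sigma, const FF &ff,
                   double *dudr) {
  if (r >= ff.rc_dh || q1q2 == 0.0) { *dudr = 0.0; return 0.0; }
  double lD = ff.lambda_D;
  double pref = q1q2 * ff.l_b * std::exp(sigma / lD) / (1.0 + sigma / lD);
  double core = pref * std::exp(-r / lD) / r;
  double dcore = -core * (1.0 / lD + 1.0 / r);
  if (r < ff.ron) { *dudr = dcore; return core; }
  double rc2 = ff.rc_dh * ff.rc_dh, ron2 = ff.ron * ff.ron, r2 = r * r;
  double denom = rc2 - ron2; denom = denom * denom * denom;
  double a = rc2 - r2;
  double s = a * a * (rc2 + 2.0 * r2 - 3.0 * ron2) / denom;
  double ds = 12.0 * r * a * (ron2 - r2) / denom;
  *dudr = dcore * s + core * ds;
  return core * s;
}

// Full pair dispatch. Returns energy; writes dU/dr and the decomposition
// bucket. cp_off disables the excluder-polymer term (permeable subunit).
inline double pair_energy(int ti, int tj, double qi, double qj, double r,
                          const FF &ff, bool cp_off,
                          double *dudr, int *bucket, long *ncap) {
  *dudr = 0.0; *bucket = B_NONE;
  if (ti > tj) { int t = ti; ti = tj; tj = t; double q = qi; qi = qj; qj = q; }
  double d1, d2;
  switch (ti) {
  case ATTR:
    if (tj == ATTR) {
      double u = ff.eps * u_morse(r, ff.r0, ff.rho, ff.rcut_morse, &d1);
      *dudr = ff.eps * d1; *bucket = B_CC; return u;
    }
    return 0.0;
  case TOP:
    if (tj == TOP) {
      double u = ff.eps * u_rep_lj(r, ff.sigma_t, ff.cap_frac, &d1, ncap);
      *dudr = ff.eps * d1; *bucket = B_CC; return u;
    }
    if (tj == BOT) {
      double u = ff.eps * u_rep_lj(r, ff.sigma_b, ff.cap_frac, &d1, ncap);
      *dudr = ff.eps * d1; *bucket = B_CC; return u;
    }
    return 0.0;
  case EXCL:
    if (tj == POLY) {
      if (cp_off) return 0.0;
      double u = u_rep_lj(r, ff.sigma_xp, ff.cap_frac, &d1, ncap);
      *dudr = d1; *bucket = B_CP; return u;
    }
    if (tj == ARM) {
      double u = u_rep_lj(r, ff.sigma_xa, ff.cap_frac, &d1, ncap);
      *dudr = d1; *bucket = B_CA; return u;
    }
    return 0.0;
  case ARM:
    if (tj == ARM) {
      double u = u_rep_lj(r, ff.sigma_a, ff.cap_frac, &d1, ncap) +
                 u_dh(r, qi * qj, ff.sigma_a, ff, &d2);
      *dudr = d1 + d2; *bucket = B_AA; return u;
    }
    if (tj == POLY) {
      double u = u_rep_lj(r, ff.sigma_ap, ff.cap_frac, &d1, ncap) +
                 u_dh(r, qi * qj, ff.sigma_ap, ff, &d2);
      *dudr = d1 + d2; *bucket = B_PA; return u;
    }
    return 0.0;
  case POLY:
    if (tj == POLY) {
      double u = u_rep_lj(r, ff.sigma_p, ff.cap_frac, &d1, ncap) +
                 u_dh(r, qi * qj, ff.sigma_p, ff, &d2);
      *dudr = d1 + d2; *bucket = B_PP; return u;
    }
    return 0.0;
  default:
    return 0.0;
  }
}

// Largest interaction range between any two of the bead types present.
inline double ff_max_cutoff(const FF &ff, const bool *present) {
  double rc = 0.0;
  auto upd = [&rc](double x) { if (x > rc) rc = x; };
  if (present[ATTR]) upd(ff.rcut_morse);
  if (present[TOP]) upd(ff.sigma_t);
  if (present[TOP] && present[BOT]) upd(ff.sigma_b);
  if (present[EXCL] && present[POLY]) upd(ff.sigma_xp);
  if (present[EXCL] && present[ARM]) upd(ff.sigma_xa);
  if (present[POLY] || present[ARM]) { upd(ff.rc_dh); upd(ff.sigma_ap); }
  return rc > 0 ? rc : 1.0;
}
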