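// System container shared by the energy, BD and sampling kernels.
#pragma once
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include "ff.h"

struct Sys {
  int N;
  std::vector<double> x, y, z;
  std::vector<int> type;
  std::vector<double> charge;
  std::vector<int> body;        // 0 = free bead
  std::vector<bool> cp_off;     // excluder bead belongs to a permeable subunit
  // bonds
  std::vector<int> b1, b2;
  std::vector<double> bond_r0, bond_k;
  // angles (harmonic in the deviation from a straight triple)
  std::vector<int> a1, a2, a3;
  std::vector<double> angle_k;
  double box;                   // <= 0: open boundaries
  std::unordered_set<int64_t> excl;  // bonded-pair nonbonded exclusions

  bool excluded(int i, int j) const {
    int64_t key = i < j ? (int64_t)i * N + j : (int64_t)j * N + i;
    return excl.count(key) > 0;
  }
};

inline FF ff_from_list(const Rcpp::List &l) {
  FF ff;
  ff.eps = Rcpp::as<double>(l["epsilon"]);
  ff.sigma_t = Rcpp::as<double>(l["sigma_t"]);
  ff.sigma_b = Rcpp::as<double>(l["sigma_b"]);
  ff.r0 = Rcpp::as<double>(l["r0"]);
  ff.rho = Rcpp::as<double>(l["rho"]);
  ff.rcut_morse = Rcpp::as<double>(l["rcut_morse"]);
  ff.sigma_p = Rcpp::as<double>(l["sigma_p"]);
  ff.sigma_x = Rcpp::as<double>(l["sigma_x"]);
  ff.sigma_a = Rcpp::as<double>(l["sigma_a"]);
  ff.lambda_D = Rcpp::as<double>(l["lambda_D"]);
  ff.l_b = Rcpp::as<double>(l["l_b"]);
  ff.cap_frac = l.containsElementNamed("cap_frac") ?
    Rcpp::as<double>(l["cap_frac"]) : 0.2;
  ff_derive(ff);
  return ff;
}

inline Sys sys_from_list(const Rcpp::List &l) {
  Sys s;
  Rcpp::NumericMatrix pos = l["pos"];
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.type = Rcpp::as<std::vector<int>>(l["type"]);
  s.charge = Rcpp::as<std::vector<double>>(l["charge"]);
  s.body = Rcpp::as<std::vector<int>>(l["body"]);
  s.box = Rcpp::as<double>(l["box"]);
  Rcpp::IntegerMatrix bonds = l["bonds"];
  int nb = bonds.nrow();
  s.b1.resize(nb); s.b2.resize(nb);
  for (int b = 0; b < nb; ++b) { s.b1[b] = bonds(b, 0) - 1; s.b2[b] = bonds(b, 1) - 1; }
  s.bond_r0 = Rcpp::as<std::vector<double>>(l["bond_r0"]);
  s.bond_k = Rcpp::as<std::vector<double>>(l["bond_k"]);
  Rcpp::IntegerMatrix ang = l["angles"];
  int na = ang.nrow();
  s.a1.resize(na); s.a2.resize(na); s.a3.resize(na);
  for (int a = 0; a < na; ++a) {
    s.a1[a] = ang(a, 0) - 1; s.a2[a] = ang(a, 1) - 1; s.a3[a] = ang(a, 2) - 1;
  }
  s.angle_k = Rcpp::as<std::vector<double>>(l["angle_k"]);
  s.cp_off.assign(s.N, false);
  if (l.containsElementNamed("permeable_bodies")) {
    std::vector<int> pb = Rcpp::as<std::vector<int>>(l["permeable_bodies"]);
    std::unordered_set<int> pbs(pb.begin(), pb.end());
    for (int i = 0; i < s.N; ++i)
      if (s.type[i] == EXCL && s.body[i] > 0 && pbs.count(s.body[i]))
        s.cp_off[i] = true;
  }
  for (int b = 0; b < nb; ++b) {
    int i = s.b1[b], j = s.b2[b];
    int64_t key = i < j ? (int64_t)i * s.N + j : (int64_t)j * s.N + i;
    s.excl.insert(key);
  }
  return s;
}

inline double min_image(double d, double box) {
  if (box > 0) d -= box * std::nearbyint(d / box);
  return d;
}

// Linked-cell neighbor grid (periodic when box > 0, otherwise over the
// bounding box of the coordinates).
struct CellGrid {
  double rc, box, ox, oy, oz;
  int nx, ny, nz;
  bool periodic;
  std::vector<int> head, nxt;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const std::vector<int> *subset,
             int N, double cutoff, double box_) {
    rc = cutoff; box = box_; periodic = box_ > 0;
    if (periodic) {
      ox = oy = oz = 0.0;
      nx = ny = nz = std::max(1, (int)std::floor(box / rc));
      if (nx < 3) { nx = ny = nz = 1; periodic = false; ox = oy = oz = -box; }
    }
    if (!periodic) {
      double xmin = 1e300, ymin = 1e300, zmin = 1e300;
      double xmax = -1e300, ymax = -1e300, zmax = -1e300;
      int n = subset ? (int)subset->size() : N;
      for (int k = 0; k < n; ++k) {
        int i = subset ? (*subset)[k] : k;
        xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
        ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
        zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
      }
      ox = xmin - rc; oy = ymin - rc; oz = zmin - rc;
      nx = std::max(1, (int)std::floor((xmax - ox + rc) / rc) + 1);
      ny = std::max(1, (int)std::floor((ymax - oy + rc) / rc) + 1);
      nz = std::max(1, (int)std::floor((zmax - oz + rc) / rc) + 1);
    }
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(N, -1);
    int n = subset ? (int)subset->size() : N;
    for (int k = 0; k < n; ++k) {
      int i = subset ? (*subset)[k] : k;
      int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c]; head[c] = i;
    }
  }

  int clampc(int c, int n) const { return c < 0 ? 0 : (c >= n ? n - 1 : c); }

  int cell_of(double px, double py, double pz) const {
    int cx, cy, cz;
    if (periodic) {
      double fx = px / box - std::floor(px / box);
      double fy = py / box - std::floor(py / box);
      double fz = pz / box - std::floor(pz / box);
      cx = std::min((int)(fx * nx), nx - 1);
      cy = std::min((int)(fy * ny), ny - 1);
      cz = std::min((int)(fz * nz), nz - 1);
    } else {
      cx = clampc((int)std::floor((px - ox) / rc), nx);
      cy = clampc((int)std::floor((py - oy) / rc), ny);
      cz = clampc((int)std::floor((pz - oz) / rc), nz);
    }
    return (cz * ny + cy) * nx + cx;
  }

  // visit all beads in the 27 cells around (px,py,pz)
  template <typename F>
  void for_neighbors(double px, double py, double pz, F f) const {
    int cx, cy, cz;
    if (periodic) {
      double fx = px / box - std::floor(px / box);
      double fy = py / box - std::floor(py / box);
      double fz = pz / box - std::floor(pz / box);
      cx = std::min((int)(fx * nx), nx - 1);
      cy = std::min((int)(fy * ny), ny - 1);
      cz = std::min((int)(fz * nz), nz - 1);
    } else {
      cx = clampc((int)std::floor((px - ox) / rc), nx);
      cy = clampc((int)std::floor((py - oy) / rc), ny);
      cz = clampc((int)std::floor((pz - oz) / rc), nz);
    }
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ccx = cx + dx, ccy = cy + dy, ccz = cz + dz;
          if (periodic) {
            ccx = (ccx + nx) % nx; ccy = (ccy + ny) % ny; ccz = (ccz + nz) % nz;
          } else if (ccx < 0 || ccy < 0 || ccz < 0 ||
                     ccx >= nx || ccy >= ny || ccz >= nz) {
            continue;
          }
          for (int j = head[(ccz * ny + ccy) * nx + ccx]; j >= 0; j = nxt[j]) f(j);
        }
  }
};

struct EnergyAcc {
  double bucket[6] = {0, 0, 0, 0, 0, 0};
  long ncap = 0;
  double total() const {
    double t = 0; for (int i = 0; i < 6; ++i) t += bucket[i]; return t;
  }
};

// Bucket for a bonded term, assigned by the bead types it joins.
inline int bonded_bucket(const Sys &s, int i, int j) {
  if (s.type[i] == ARM || s.type[j] == ARM) return B_AA;
  return B_PP;
}

// Pair part of the energy (and forces when fx != nullptr).
//
// The interaction matrix has no terms between the long-range rigid-body
// types (attractor/Top/Bottom, cutoffs up to sigma_t) and the short-range
// bead types (excluder/ARM/polymer, cutoffs ~ max(sigma_x, 3 lambda_D)).
// The two groups are therefore handled separately: the small rigid-body
// group with an all-pairs loop, the bead group with a linked-cell grid at
// its own (much smaller) cutoff.
inline void accumulate_pairs(const Sys &s, const FF &ff, EnergyAcc &acc,
                             std::vector<double> *fx, std::vector<double> *fy,
                             std::vector<double> *fz, bool naive) {
  auto do_pair = [&](int i, int j, double rc2) {
    if (s.body[i] > 0 && s.body[i] == s.body[j]) return;
    if (s.type[i] == INERT || s.type[j] == INERT) return;
    double dx = min_image(s.x[i] - s.x[j], s.box);
    double dy = min_image(s.y[i] - s.y[j], s.box);
    double dz = min_image(s.z[i] - s.z[j], s.box);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    if (s.excluded(i, j)) return;
    double r = std::sqrt(r2);
    if (r < 1e-12) r = 1e-12;
    double dudr; int bucket;
    bool cp_off = s.cp_off[i] || s.cp_off[j];
    double u = pair_energy(s.type[i], s.type[j], s.charge[i], s.charge[j], r,
                           ff, cp_off, &dudr, &bucket, &acc.ncap);
    if (bucket >= 0) acc.bucket[bucket] += u;
    if (fx && dudr != 0.0) {
      double fmag = -dudr / r;
      (*fx)[i] += fmag * dx; (*fy)[i] += fmag * dy; (*fz)[i] += fmag * dz;
      (*fx)[j] -= fmag * dx; (*fy)[j] -= fmag * dy; (*fz)[j] -= fmag * dz;
    }
  };
  bool present[7] = {false, false, false, false, false, false, false};
  for (int i = 0; i < s.N; ++i) present[s.type[i]] = true;
  double rc_all = ff_max_cutoff(ff, present);
  if (naive || s.N < 64) {
    double rc2 = rc_all * rc_all;
    for (int i = 0; i < s.N; ++i)
      for (int j = i + 1; j < s.N; ++j) do_pair(i, j, rc2);
    return;
  }
  std::vector<int> ga, gb;
  ga.reserve(s.N); gb.reserve(s.N);
  for (int i = 0; i < s.N; ++i) {
    if (s.type[i] <= BOT) ga.push_back(i);
    else if (s.type[i] != INERT) gb.push_back(i);
  }
  double rc_a = std::max(ff.rcut_morse, std::max(ff.sigma_t, ff.sigma_b));
  double rc2_a = rc_a * rc_a;
  for (size_t a = 0; a < ga.size(); ++a)
    for (size_t b = a + 1; b < ga.size(); ++b) do_pair(ga[a], ga[b], rc2_a);
  if (!gb.empty()) {
    double rc_b = std::max(std::max(ff.sigma_xp, ff.sigma_xa), ff.rc_dh);
    double rc2_b = rc_b * rc_b;
    if (s.box > 0 && s.box < 3 * rc_b) {
      // box too small for a periodic grid: all-pairs within the group
      for (size_t a = 0; a < gb.size(); ++a)
        for (size_t b = a + 1; b < gb.size(); ++b)
          do_pair(gb[a], gb[b], rc2_b);
    } else {
      CellGrid g;
      g.build(s.x, s.y, s.z, &gb, s.N, rc_b, s.box);
      for (int i : gb)
        g.for_neighbors(s.x[i], s.y[i], s.z[i], [&](int j) {
          if (j > i) do_pair(i, j, rc2_b);
        });
    }
  }
}

// Bond + angle terms (no minimum image: bonded neighbors are kept unwrapped).
inline void accumulate_bonded(const Sys &s, const FF &ff, EnergyAcc &acc,
                              std::vector<double> *fx, std::vector<double> *fy,
                              std::vector<double> *fz) {
  (void)ff;
  for (size_t b = 0; b < s.b1.size(); ++b) {
    int i = s.b1[b], j = s.b2[b];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    double dr = r - s.bond_r0[b];
    acc.bucket[bonded_bucket(s, i, j)] += 0.5 * s.bond_k[b] * dr * dr;
    if (fx) {
      double fmag = -s.bond_k[b] * dr / r;
      (*fx)[i] += fmag * dx; (*fy)[i] += fmag * dy; (*fz)[i] += fmag * dz;
      (*fx)[j] -= fmag * dx; (*fy)[j] -= fmag * dy; (*fz)[j] -= fmag * dz;
    }
  }
  for (size_t a = 0; a < s.a1.size(); ++a) {
    int i = s.a1[a], j = s.a2[a], k = s.a3[a];
    double r1x = s.x[i] - s.x[j], r1y = s.y[i] - s.y[j], r1z = s.z[i] - s.z[j];
    double r2x = s.x[k] - s.x[j], r2y = s.y[k] - s.y[j], r2z = s.z[k] - s.z[j];
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    double cosq = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    cosq = std::max(-1.0, std::min(1.0, cosq));
    double theta = std::acos(cosq);        // interior angle; straight = pi
    double dev = M_PI - theta;             // deviation from a straight triple
    acc.bucket[bonded_bucket(s, i, j)] += 0.5 * s.angle_k[a] * dev * dev;
    if (fx) {
      // dU/dtheta = -k * dev ; force via standard angle gradient
      double sinq = std::sqrt(std::max(1e-12, 1.0 - cosq * cosq));
      double coef = -s.angle_k[a] * dev / sinq;  // dU/dcos(theta) factor sign
      // grad_i cos = (r2/ (n1 n2)) - cos * r1 / n1^2
      double gix = r2x / (n1 * n2) - cosq * r1x / (n1 * n1);
      double giy = r2y / (n1 * n2) - cosq * r1y / (n1 * n1);
      double giz = r2z / (n1 * n2) - cosq * r1z / (n1 * n1);
      double gkx = r1x / (n1 * n2) - cosq * r2x / (n2 * n2);
      double gky = r1y / (n1 * n2) - cosq * r2y / (n2 * n2);
      double gkz = r1z / (n1 * n2) - cosq * r2z / (n2 * n2);
      // dU/dcos = dU/dtheta * dtheta/dcos = (-k dev) * (-1/sin) = k dev / sin
      double duc = s.angle_k[a] * dev / sinq;
      // regularize the fold-back singularity (theta -> 0); such states cost
      // ~k pi^2 / 2 kBT and are unreachable in equilibrium
      double cap = 1000.0 * s.angle_k[a];
      if (duc > cap) duc = cap;
      (void)coef;
      (*fx)[i] -= duc * gix; (*fy)[i] -= duc * giy; (*fz)[i] -= duc * giz;
      (*fx)[k] -= duc * gkx; (*fy)[k] -= duc * gky; (*fz)[k] -= duc * gkz;
      (*fx)[j] += duc * (gix + gkx);
      (*fy)[j] += duc * (giy + gky);
      (*fz)[j] += duc * (giz + gkz);
    }
  }
}
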