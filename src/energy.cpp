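#include <Rcpp.h>
#include "sys.h"
using namespace Rcpp;

static List energy_report(const EnergyAcc &acc) {
  return List::create(
    _["u_cc"] = acc.bucket[B_CC], _["u_cp"] = acc.bucket[B_CP],
    _["u_ca"] = acc.bucket[B_CA], _["u_pp"] = acc.bucket[B_PP],
    _["u_pa"] = acc.bucket[B_PA], _["u_aa"] = acc.bucket[B_AA],
    _["total"] = acc.total(), _["n_capped"] = (double)acc.ncap);
}

// [[Rcpp::export]]
List cs_energy(List sys, List ff, bool naive = false) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  EnergyAcc acc;
  accumulate_pairs(s, f, acc, nullptr, nullptr, nullptr, naive);
  accumulate_bonded(s, f, acc, nullptr, nullptr, nullptr);
  return energy_report(acc);
}

// [[Rcpp::export]]
List cs_forces(List sys, List ff, bool naive = false) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  EnergyAcc acc;
  std::vector<double> fx(s.N, 0.0), fy(s.N, 0.0), fz(s.N, 0.0);
  accumulate_pairs(s, f, acc, &fx, &fy, &fz, naive);
  accumulate_bonded(s, f, acc, &fx, &fy, &fz);
  NumericMatrix F(s.N, 3);
  for (int i = 0; i < s.N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = energy_report(acc));
}

// Energy of a single probe bead against the whole system (Widom-style).
// exclude: 1-based indices whose nonbonded interaction with the probe is
// skipped (e.g. the chain end the probe is bonded to).
// [[Rcpp::export]]
double cs_probe_energy(List sys, List ff, NumericVector xyz, int type,
                       double charge, IntegerVector exclude) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  std::unordered_set<int> ex;
  for (int k = 0; k < exclude.size(); ++k) ex.insert(exclude[k] - 1);
  double u = 0.0; long ncap = 0;
  for (int j = 0; j < s.N; ++j) {
    if (ex.count(j)) continue;
    double dx = min_image(xyz[0] - s.x[j], s.box);
    double dy = min_image(xyz[1] - s.y[j], s.box);
    double dz = min_image(xyz[2] - s.z[j], s.box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    double dudr; int bucket;
    u += pair_energy(type, s.type[j], charge, s.charge[j], r, f,
                     s.cp_off[j], &dudr, &bucket, &ncap);
  }
  return u;
}

// Overlap relaxation: capped steepest descent on the full potential. Moves
// free beads and rigid bodies (as rigid translations) until overlaps relax.
// [[Rcpp::export]]
List cs_pushoff(List sys, List ff, int n_iter = 200, double max_step = 0.05,
                bool move_bodies = true) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  int nbody = 0;
  for (int i = 0; i < s.N; ++i) nbody = std::max(nbody, s.body[i]);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    EnergyAcc acc;
    accumulate_pairs(s, f, acc, &fx, &fy, &fz, false);
    accumulate_bonded(s, f, acc, &fx, &fy, &fz);
    std::vector<double> bfx(nbody + 1, 0.0), bfy(nbody + 1, 0.0),
        bfz(nbody + 1, 0.0);
    std::vector<int> bn(nbody + 1, 0);
    for (int i = 0; i < s.N; ++i)
      if (s.body[i] > 0) {
        bfx[s.body[i]] += fx[i]; bfy[s.body[i]] += fy[i];
        bfz[s.body[i]] += fz[i]; bn[s.body[i]]++;
      }
    for (int i = 0; i < s.N; ++i) {
      double gx, gy, gz;
      if (s.body[i] > 0 && !move_bodies) continue;
      if (s.body[i] > 0) {
        gx = bfx[s.body[i]] / bn[s.body[i]];
        gy = bfy[s.body[i]] / bn[s.body[i]];
        gz = bfz[s.body[i]] / bn[s.body[i]];
      } else { gx = fx[i]; gy = fy[i]; gz = fz[i]; }
      double fm = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (fm < 1e-12) continue;
      double step = std::min(max_step, 1e-3 * fm);
      s.x[i] += step * gx / fm; s.y[i] += step * gy / fm; s.z[i] += step * gz / fm;
    }
  }
  NumericMatrix pos(s.N, 3);
  for (int i = 0; i < s.N; ++i) { pos(i, 0) = s.x[i]; pos(i, 1) = s.y[i]; pos(i, 2) = s.z[i]; }
  EnergyAcc acc;
  accumulate_pairs(s, f, acc, nullptr, nullptr, nullptr, false);
  accumulate_bonded(s, f, acc, nullptr, nullptr, nullptr);
  return List::create(_["pos"] = pos, _["energy"] = energy_report(acc));
}
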