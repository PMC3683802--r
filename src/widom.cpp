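// Widom chain-increment insertions: a test polymer segment is inserted at a
// chain end with a bond length drawn from a truncated normal and a uniformly
// random direction; the insertion energy (nonbonded against the whole system
// plus the new angle term) is returned per trial for a-posteriori
// non-Boltzmann reweighting on the R side.
#include <Rcpp.h>
#include <random>
#include "sys.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cs_widom(List sys, List ff, int end_index, int prev_index,
              double bond_r0, double bond_k, double kangle, double beta,
              int n_insert, int seed, double trunc_sd = 3.0) {
  Sys s = sys_from_list(sys);
  FF f = ff_from_list(ff);
  int e = end_index - 1, p = prev_index - 1;  // p = -1 when chain length 1
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double sd = std::sqrt(1.0 / (beta * bond_k));

  bool present[7] = {false, false, false, false, false, false, false};
  for (int i = 0; i < s.N; ++i) present[s.type[i]] = true;
  present[POLY] = true;
  double rc = ff_max_cutoff(f, present);
  CellGrid g;
  bool use_grid = s.N >= 64;
  if (use_grid) g.build(s.x, s.y, s.z, nullptr, s.N, rc, s.box);

  NumericVector ui(n_insert), ls(n_insert);
  NumericMatrix xyz(n_insert, 3);
  for (int t = 0; t < n_insert; ++t) {
    double l;
    do { l = bond_r0 + sd * gauss(rng); } while (std::fabs(l - bond_r0) > trunc_sd * sd || l <= 0);
    double cth = 2 * unif(rng) - 1, ph = 2 * M_PI * unif(rng);
    double sth = std::sqrt(1 - cth * cth);
    double px = s.x[e] + l * sth * std::cos(ph);
    double py = s.y[e] + l * sth * std::sin(ph);
    double pz = s.z[e] + l * cth;
    double u = 0.0;
    long ncap = 0;
    auto addj = [&](int j) {
      if (j == e) return;  // bonded neighbor: excluded nonbonded pair
      double dx = min_image(px - s.x[j], s.box);
      double dy = min_image(py - s.y[j], s.box);
      double dz = min_image(pz - s.z[j], s.box);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= rc) return;
      if (r < 1e-12) r = 1e-12;
      double dudr; int bucket;
      u += pair_energy(POLY, s.type[j], -1.0, s.charge[j], r, f,
                       s.cp_off[j], &dudr, &bucket, &ncap);
    };
    if (use_grid) g.for_neighbors(px, py, pz, addj);
    else for (int j = 0; j < s.N; ++j) addj(j);
    if (p >= 0 && kangle > 0) {
      double r1x = s.x[p] - s.x[e], r1y = s.y[p] - s.y[e], r1z = s.z[p] - s.z[e];
      double r2x = px - s.x[e], r2y = py - s.y[e], r2z = pz - s.z[e];
      double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * l);
      c = std::max(-1.0, std::min(1.0, c));
      double dev = M_PI - std::acos(c);
      u += 0.5 * kangle * dev * dev;
    }
    ui[t] = u; ls[t] = l;
    xyz(t, 0) = px; xyz(t, 1) = py; xyz(t, 2) = pz;
  }
  return List::create(_["ui"] = ui, _["l"] = ls, _["xyz"] = xyz);
}
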