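// Metropolis Monte Carlo for an unconfined (possibly base-paired) polymer
// under the model force field: local bead displacements, crankshaft rotations
// of base-pair-closed intervals about their anchor axis, and end pivots.
// Interval moves exploit the pseudoknot-free (nested) pairing: an interval
// whose interior base pairs all stay inside it can be rotated rigidly with
// only the two anchor angles and the moved/fixed cross energy changing.
#include <Rcpp.h>
#include <random>
#include "sys.h"
using namespace Rcpp;

struct RangeMM {
  int n = 0;
  std::vector<std::vector<int>> mn, mx;
  void build(const std::vector<int> &lo, const std::vector<int> &hi) {
    n = lo.size();
    int L = 1; while ((1 << L) <= n) ++L;
    mn.assign(L, lo); mx.assign(L, hi);
    for (int l = 1; l < L; ++l)
      for (int i = 0; i + (1 << l) <= n; ++i) {
        mn[l][i] = std::min(mn[l - 1][i], mn[l - 1][i + (1 << (l - 1))]);
        mx[l][i] = std::max(mx[l - 1][i], mx[l - 1][i + (1 << (l - 1))]);
      }
  }
  int qmin(int l, int r) const {  // inclusive, l <= r
    int k = 31 - __builtin_clz(r - l + 1);
    return std::min(mn[k][l], mn[k][r - (1 << k) + 1]);
  }
  int qmax(int l, int r) const {
    int k = 31 - __builtin_clz(r - l + 1);
    return std::max(mx[k][l], mx[k][r - (1 << k) + 1]);
  }
};

struct MCState {
  int N;
  std::vector<double> x, y, z, charge;
  std::vector<int> partner;  // -1 = unpaired
  std::vector<int> ang_of_center;  // angle index by center bead, -1 = none
  std::vector<int> a1, a2, a3;
  std::vector<double> angle_k;
  std::vector<int> b1, b2;
  std::vector<double> bond_r0, bond_k;
  std::vector<std::vector<int>> bonds_of;
  FF ff;
  double beta;
  RangeMM rmm;

  bool excluded_nb(int i, int j) const {
    return j == i + 1 || j == i - 1 || partner[i] == j;
  }
  double pair_nb(int i, double px, double py, double pz, int j) const {
    double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    double dudr; int bucket; long ncap = 0;
    return pair_energy(POLY, POLY, charge[i], charge[j], r, ff, false,
                       &dudr, &bucket, &ncap);
  }
  double bond_e(int b) const {
    int i = b1[b], j = b2[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - bond_r0[b];
    return 0.5 * bond_k[b] * d * d;
  }
  double angle_e(int a) const {
    if (a < 0) return 0.0;
    int i = a1[a], j = a2[a], k = a3[a];
    double r1x = x[i] - x[j], r1y = y[i] - y[j], r1z = z[i] - z[j];
    double r2x = x[k] - x[j], r2y = y[k] - y[j], r2z = z[k] - z[j];
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    c = std::max(-1.0, std::min(1.0, c));
    double dev = M_PI - std::acos(c);
    return 0.5 * angle_k[a] * dev * dev;
  }
  // closure: every interior bead's partner lies within [lo-1, hi+1] anchors
  bool closed(int ilo, int ihi, int alo, int ahi) const {
    if (ilo > ihi) return true;
    return rmm.qmin(ilo, ihi) >= alo && rmm.qmax(ilo, ihi) <= ahi;
  }
  double total_energy() const {
    double e = 0.0;
    double rc = std::max(ff.rc_dh, std::max(ff.sigma_p, ff.sigma_ap));
    CellGrid g;
    g.build(x, y, z, nullptr, N, rc, -1.0);
    for (int i = 0; i < N; ++i)
      g.for_neighbors(x[i], y[i], z[i], [&](int j) {
        if (j > i && !excluded_nb(i, j)) e += pair_nb(i, x[i], y[i], z[i], j);
      });
    for (size_t b = 0; b < b1.size(); ++b) e += bond_e(b);
    for (size_t a = 0; a < a1.size(); ++a) e += angle_e(a);
    return e;
  }
};

static void rotate_about(double &px, double &py, double &pz,
                         double ox, double oy, double oz,
                         double ux, double uy, double uz, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  double vx = px - ox, vy = py - oy, vz = pz - oz;
  double d = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  px = ox + vx * c + cx * s + ux * d * (1 - c);
  py = oy + vy * c + cy * s + uy * d * (1 - c);
  pz = oz + vz * c + cz * s + uz * d * (1 - c);
}

// [[Rcpp::export]]
List cs_mc_polymer(NumericMatrix pos, NumericVector charge,
                   IntegerVector partner, IntegerMatrix bonds,
                   NumericVector bond_r0, NumericVector bond_k,
                   IntegerMatrix angles, NumericVector angle_k, List ff,
                   double beta, double n_moves, int seed,
                   double sample_stride = 200, double frame_stride = 0,
                   double local_disp = 0.3, double max_angle = 3.14159265358979,
                   double p_local = 0.3) {
  MCState st;
  st.N = pos.nrow();
  st.x.resize(st.N); st.y.resize(st.N); st.z.resize(st.N);
  for (int i = 0; i < st.N; ++i) {
    st.x[i] = pos(i, 0); st.y[i] = pos(i, 1); st.z[i] = pos(i, 2);
  }
  st.charge = as<std::vector<double>>(charge);
  st.partner.resize(st.N);
  for (int i = 0; i < st.N; ++i) st.partner[i] = partner[i] - 1;  // -1 if 0
  st.ff = ff_from_list(ff);
  st.beta = beta;
  int nb = bonds.nrow();
  st.b1.resize(nb); st.b2.resize(nb);
  st.bonds_of.assign(st.N, {});
  for (int b = 0; b < nb; ++b) {
    st.b1[b] = bonds(b, 0) - 1; st.b2[b] = bonds(b, 1) - 1;
    st.bonds_of[st.b1[b]].push_back(b);
    st.bonds_of[st.b2[b]].push_back(b);
  }
  st.bond_r0 = as<std::vector<double>>(bond_r0);
  st.bond_k = as<std::vector<double>>(bond_k);
  int na = angles.nrow();
  st.a1.resize(na); st.a2.resize(na); st.a3.resize(na);
  st.ang_of_center.assign(st.N, -1);
  for (int a = 0; a < na; ++a) {
    st.a1[a] = angles(a, 0) - 1; st.a2[a] = angles(a, 1) - 1;
    st.a3[a] = angles(a, 2) - 1;
    st.ang_of_center[st.a2[a]] = a;
  }
  st.angle_k = as<std::vector<double>>(angle_k);
  std::vector<int> pmin(st.N), pmax(st.N);
  for (int i = 0; i < st.N; ++i) {
    pmin[i] = st.partner[i] < 0 ? i : std::min(i, st.partner[i]);
    pmax[i] = st.partner[i] < 0 ? i : std::max(i, st.partner[i]);
  }
  st.rmm.build(pmin, pmax);

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto runif_int = [&](int n) { return (int)(unif(rng) * n) % n; };

  double rc = std::max(st.ff.rc_dh, st.ff.sigma_p);
  double e_run = st.total_energy();
  std::vector<double> rg_samples, e_samples;
  List frames;
  double n_acc_local = 0, n_try_local = 0, n_acc_int = 0, n_try_int = 0;
  long nm = (long)n_moves;
  long sstride = sample_stride > 0 ? (long)sample_stride : nm;
  long fstride = frame_stride > 0 ? (long)frame_stride : 0;
  CellGrid grid;
  std::vector<int> fixed_idx;
  std::vector<double> nx, ny, nz;  // proposed coords of moved beads

  for (long mv = 1; mv <= nm; ++mv) {
    if (unif(rng) < p_local) {
      // single-bead displacement
      ++n_try_local;
      int b = runif_int(st.N);
      double ox = st.x[b], oy = st.y[b], oz = st.z[b];
      double px = ox + local_disp * (2 * unif(rng) - 1);
      double py = oy + local_disp * (2 * unif(rng) - 1);
      double pz = oz + local_disp * (2 * unif(rng) - 1);
      double de = 0.0;
      for (int bi : st.bonds_of[b]) de -= st.bond_e(bi);
      for (int c = b - 1; c <= b + 1; ++c)
        if (c >= 0 && c < st.N) de -= st.angle_e(st.ang_of_center[c]);
      for (int j = 0; j < st.N; ++j) {
        if (j == b || st.excluded_nb(b, j)) continue;
        double dx = ox - st.x[j], dy = oy - st.y[j], dz = oz - st.z[j];
        if (dx * dx + dy * dy + dz * dz < rc * rc)
          de -= st.pair_nb(b, ox, oy, oz, j);
        dx = px - st.x[j]; dy = py - st.y[j]; dz = pz - st.z[j];
        if (dx * dx + dy * dy + dz * dz < rc * rc)
          de += st.pair_nb(b, px, py, pz, j);
      }
      st.x[b] = px; st.y[b] = py; st.z[b] = pz;
      for (int bi : st.bonds_of[b]) de += st.bond_e(bi);
      for (int c = b - 1; c <= b + 1; ++c)
        if (c >= 0 && c < st.N) de += st.angle_e(st.ang_of_center[c]);
      if (de <= 0.0 || unif(rng) < std::exp(-st.beta * de)) {
        e_run += de; ++n_acc_local;
      } else {
        st.x[b] = ox; st.y[b] = oy; st.z[b] = oz;
      }
    } else {
      // interval move: crankshaft (interior) or end pivot
      int mlo, mhi;          // moved beads, inclusive
      double ox_, oy_, oz_, ux, uy, uz;
      bool ok = true;
      if (unif(rng) < 0.5 && st.N > 3) {
        // crankshaft about the anchor axis (i, j)
        int i = runif_int(st.N - 2);
        int j = i + 2 + runif_int(st.N - i - 2);
        if (!st.closed(i + 1, j - 1, i, j)) ok = false;
        else {
          double ax = st.x[j] - st.x[i], ay = st.y[j] - st.y[i],
                 az = st.z[j] - st.z[i];
          double an = std::sqrt(ax * ax + ay * ay + az * az);
          if (an < 1e-9) ok = false;
          else {
            ux = ax / an; uy = ay / an; uz = az / an;
            ox_ = st.x[i]; oy_ = st.y[i]; oz_ = st.z[i];
            mlo = i + 1; mhi = j - 1;
          }
        }
      } else {
        // end pivot about a random axis through bead p
        int p = 1 + runif_int(st.N - 2);
        bool tail = unif(rng) < 0.5;
        if (tail) { mlo = p + 1; mhi = st.N - 1; }
        else { mlo = 0; mhi = p - 1; }
        if (!st.closed(mlo, mhi, tail ? p : 0, tail ? st.N - 1 : p)) ok = false;
        else {
          double th = std::acos(2 * unif(rng) - 1), ph = 2 * M_PI * unif(rng);
          ux = std::sin(th) * std::cos(ph);
          uy = std::sin(th) * std::sin(ph);
          uz = std::cos(th);
          ox_ = st.x[p]; oy_ = st.y[p]; oz_ = st.z[p];
        }
      }
      if (ok && mlo <= mhi) {
        ++n_try_int;
        double ang = max_angle * (2 * unif(rng) - 1);
        int nmoved = mhi - mlo + 1;
        nx.resize(nmoved); ny.resize(nmoved); nz.resize(nmoved);
        for (int k = 0; k < nmoved; ++k) {
          nx[k] = st.x[mlo + k]; ny[k] = st.y[mlo + k]; nz[k] = st.z[mlo + k];
          rotate_about(nx[k], ny[k], nz[k], ox_, oy_, oz_, ux, uy, uz, ang);
        }
        // cross energy against the fixed set, via a grid over fixed beads
        fixed_idx.clear();
        for (int j = 0; j < st.N; ++j)
          if (j < mlo || j > mhi) fixed_idx.push_back(j);
        double de = 0.0;
        if (!fixed_idx.empty()) {
          grid.build(st.x, st.y, st.z, &fixed_idx, st.N, rc, -1.0);
          for (int k = 0; k < nmoved; ++k) {
            int m = mlo + k;
            grid.for_neighbors(st.x[m], st.y[m], st.z[m], [&](int j) {
              if (!st.excluded_nb(m, j))
                de -= st.pair_nb(m, st.x[m], st.y[m], st.z[m], j);
            });
            grid.for_neighbors(nx[k], ny[k], nz[k], [&](int j) {
              if (!st.excluded_nb(m, j))
                de += st.pair_nb(m, nx[k], ny[k], nz[k], j);
            });
          }
        }
        // anchor angles
        int ca = mlo - 1, cb = mhi + 1;
        double ea_old = 0.0;
        if (ca >= 0) ea_old += st.angle_e(st.ang_of_center[ca]);
        if (cb < st.N) ea_old += st.angle_e(st.ang_of_center[cb]);
        std::vector<double> sx(nmoved), sy(nmoved), sz(nmoved);
        for (int k = 0; k < nmoved; ++k) {
          sx[k] = st.x[mlo + k]; sy[k] = st.y[mlo + k]; sz[k] = st.z[mlo + k];
          st.x[mlo + k] = nx[k]; st.y[mlo + k] = ny[k]; st.z[mlo + k] = nz[k];
        }
        double ea_new = 0.0;
        if (ca >= 0) ea_new += st.angle_e(st.ang_of_center[ca]);
        if (cb < st.N) ea_new += st.angle_e(st.ang_of_center[cb]);
        de += ea_new - ea_old;
        if (de <= 0.0 || unif(rng) < std::exp(-st.beta * de)) {
          e_run += de; ++n_acc_int;
        } else {
          for (int k = 0; k < nmoved; ++k) {
            st.x[mlo + k] = sx[k]; st.y[mlo + k] = sy[k]; st.z[mlo + k] = sz[k];
          }
        }
      }
    }
    if (mv % sstride == 0) {
      double cxm = 0, cym = 0, czm = 0;
      for (int i = 0; i < st.N; ++i) { cxm += st.x[i]; cym += st.y[i]; czm += st.z[i]; }
      cxm /= st.N; cym /= st.N; czm /= st.N;
      double rg2 = 0;
      for (int i = 0; i < st.N; ++i) {
        double dx = st.x[i] - cxm, dy = st.y[i] - cym, dz = st.z[i] - czm;
        rg2 += dx * dx + dy * dy + dz * dz;
      }
      rg_samples.push_back(std::sqrt(rg2 / st.N));
      e_samples.push_back(e_run);
    }
    if (fstride > 0 && mv % fstride == 0) {
      NumericMatrix P(st.N, 3);
      for (int i = 0; i < st.N; ++i) {
        P(i, 0) = st.x[i]; P(i, 1) = st.y[i]; P(i, 2) = st.z[i];
      }
      frames.push_back(P);
    }
  }
  NumericMatrix P(st.N, 3);
  for (int i = 0; i < st.N; ++i) { P(i, 0) = st.x[i]; P(i, 1) = st.y[i]; P(i, 2) = st.z[i]; }
  return List::create(
    _["pos"] = P, _["rg"] = NumericVector(rg_samples.begin(), rg_samples.end()),
    _["energy"] = NumericVector(e_samples.begin(), e_samples.end()),
    _["frames"] = frames,
    _["accept_local"] = n_try_local > 0 ? n_acc_local / n_try_local : NA_REAL,
    _["accept_interval"] = n_try_int > 0 ? n_acc_int / n_try_int : NA_REAL,
    _["final_energy_running"] = e_run,
    _["final_energy_exact"] = st.total_energy());
}
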