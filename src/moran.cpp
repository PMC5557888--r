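// Minimal hierarchical Moran process: replicators carrying a cooperativity
// pair (k1, k2) partitioned into protocells that split when their size
// exceeds V. Each step: one fitness-proportional birth, one uniform death
// (population size exactly constant). Fitness
//   f = exp(kbar1 + kbar2 - r (k1 + k2))
// with the per-cell means kbar taken over the replicator's protocell. In the
// "rectified" variance mode every k entering f is clamped at 0 from below
// (so df/dk_i = 0 for k_i < 0); in the "invariant" mode no clamping is done
// and the mutational variance of f does not vanish near k = 0.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int MODE_RECTIFIED = 0;
const int MODE_INVARIANT = 1;

struct MoranCell {
  std::vector<int> mem;
  double S1, S2;   // sums of (possibly clamped) k1, k2 over members
  double G;        // sum of exp(-r * g_i)
};

struct Moran {
  double r, m, delta, k_upper;
  int V, mode;
  bool within_cell_death;
  std::vector<double> k1, k2;
  std::vector<int> cellOf, posInCell;
  std::vector<MoranCell> cells;

  double cval(double k) const { return (mode == MODE_RECTIFIED && k < 0.0) ? 0.0 : k; }
  double gval(int i) const {
    double g = -r * (cval(k1[i]) + cval(k2[i]));
    if (g > 50.0) g = 50.0; else if (g < -50.0) g = -50.0;
    return g;
  }

  void addTo(int i, int c) {
    cellOf[i] = c;
    posInCell[i] = (int)cells[c].mem.size();
    cells[c].mem.push_back(i);
    cells[c].S1 += cval(k1[i]);
    cells[c].S2 += cval(k2[i]);
    cells[c].G += std::exp(gval(i));
  }

  void removeFrom(int i) {
    int c = cellOf[i];
    MoranCell& cc = cells[c];
    cc.S1 -= cval(k1[i]);
    cc.S2 -= cval(k2[i]);
    cc.G -= std::exp(gval(i));
    int last = cc.mem.back();
    cc.mem[posInCell[i]] = last;
    posInCell[last] = posInCell[i];
    cc.mem.pop_back();
  }

  void rebuildCellSums(int c) { // guard against drift of incremental sums
    MoranCell& cc = cells[c];
    cc.S1 = cc.S2 = cc.G = 0.0;
    for (size_t j = 0; j < cc.mem.size(); ++j) {
      int i = cc.mem[j];
      cc.S1 += cval(k1[i]);
      cc.S2 += cval(k2[i]);
      cc.G += std::exp(gval(i));
    }
  }

  double cellWeight(int c) const {
    const MoranCell& cc = cells[c];
    if (cc.mem.empty()) return 0.0;
    double M = (cc.S1 + cc.S2) / (double)cc.mem.size();
    if (M > 50.0) M = 50.0; else if (M < -50.0) M = -50.0;
    return std::exp(M) * cc.G;
  }

  void dropCellIfEmpty(int c) {
    if (!cells[c].mem.empty()) return;
    int last = (int)cells.size() - 1;
    if (c != last) {
      cells[c] = cells[last];
      for (size_t j = 0; j < cells[c].mem.size(); ++j) cellOf[cells[c].mem[j]] = c;
    }
    cells.pop_back();
  }

  void mutate(double& k) {
    if (unif_rand() < m) {
      k += (-delta + 2.0 * delta * unif_rand());
      if (R_FINITE(k_upper)) while (k > k_upper) k = 2.0 * k_upper - k;
    }
  }

  // one birth-death step; returns cell index of the birth
  int stepOnce() {
    int n = (int)k1.size();
    // death victim chosen uniformly (before the birth is placed)
    int victim = (int)(unif_rand() * n);
    if (victim >= n) victim = n - 1;
    // birth: cell by weight, then individual within cell by exp(-r g)
    double W = 0.0;
    for (size_t c = 0; c < cells.size(); ++c) W += cellWeight((int)c);
    double u = unif_rand() * W;
    int bc = (int)cells.size() - 1;
    double acc = 0.0;
    for (size_t c = 0; c < cells.size(); ++c) {
      acc += cellWeight((int)c);
      if (u <= acc) { bc = (int)c; break; }
    }
    MoranCell& cc = cells[bc];
    double u2 = unif_rand() * cc.G;
    int parent = cc.mem.back();
    double acc2 = 0.0;
    for (size_t j = 0; j < cc.mem.size(); ++j) {
      acc2 += std::exp(gval(cc.mem[j]));
      if (u2 <= acc2) { parent = cc.mem[j]; break; }
    }
    if (within_cell_death) {
      int vj = (int)(unif_rand() * cc.mem.size());
      if (vj >= (int)cc.mem.size()) vj = (int)cc.mem.size() - 1;
      victim = cc.mem[vj];
    }
    double nk1 = k1[parent], nk2 = k2[parent];
    mutate(nk1); mutate(nk2);
    int vc = cellOf[victim];
    removeFrom(victim);
    k1[victim] = nk1; k2[victim] = nk2;
    addTo(victim, bc);
    // only the victim's cell can have been emptied; addTo never empties one,
    // and dropCellIfEmpty's swap keeps cellOf consistent
    dropCellIfEmpty(vc);
    return cellOf[victim];
  }

  void maybeDivide(int c) {
    if ((int)cells[c].mem.size() <= V) return;
    cells.push_back(MoranCell());
    cells.back().S1 = cells.back().S2 = cells.back().G = 0.0;
    int d = (int)cells.size() - 1;
    std::vector<int> snap = cells[c].mem;
    for (size_t j = 0; j < snap.size(); ++j) {
      if (unif_rand() < 0.5) {
        int i = snap[j];
        removeFrom(i);
        addTo(i, d);
      }
    }
    dropCellIfEmpty(d);
    dropCellIfEmpty(c);
  }
};

} // namespace

// [[Rcpp::export]]
List cppRunMinimal(NumericVector k1, NumericVector k2, IntegerVector cell,
                   List par, double steps, double stride) {
  Moran mo;
  mo.r = as<double>(par["r"]);
  mo.m = as<double>(par["m"]);
  mo.delta = as<double>(par["delta"]);
  mo.k_upper = as<double>(par["k_upper"]);
  mo.V = as<int>(par["V"]);
  mo.mode = as<int>(par["variance_mode_code"]);
  mo.within_cell_death = as<bool>(par["within_cell_death"]);
  int n = k1.size();
  int ncell0 = max(cell);
  mo.k1.assign(k1.begin(), k1.end());
  mo.k2.assign(k2.begin(), k2.end());
  mo.cellOf.assign(n, -1);
  mo.posInCell.assign(n, -1);
  mo.cells.resize(ncell0);
  for (int c = 0; c < ncell0; ++c) mo.cells[c].S1 = mo.cells[c].S2 = mo.cells[c].G = 0.0;
  for (int i = 0; i < n; ++i) mo.addTo(i, cell[i] - 1);
  for (size_t c = mo.cells.size(); c-- > 0;) mo.dropCellIfEmpty((int)c);

  long long nsteps = (long long)steps, str = (long long)stride;
  if (str < 1) str = 1;
  int nrow = (int)(nsteps / str) + 2;
  NumericMatrix traj(nrow, 5);
  int row = 0;
  long long rebuildEvery = 100000;
  for (long long t = 0; t <= nsteps; ++t) {
    if (t > 0) {
      int bc = mo.stepOnce();
      mo.maybeDivide(bc);
      if (t % rebuildEvery == 0)
        for (size_t c = 0; c < mo.cells.size(); ++c) mo.rebuildCellSums((int)c);
    }
    if ((t % str == 0 || t == nsteps) && row < nrow) {
      if (t % str != 0 && t == nsteps) { /* final row */ }
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) { s1 += mo.k1[i]; s2 += mo.k2[i]; }
      double m1 = s1 / n, m2 = s2 / n;
      double c1 = m1 > 0 ? m1 : 0.0, c2 = m2 > 0 ? m2 : 0.0;
      double den = c1 + c2;
      traj(row, 0) = (double)t;
      traj(row, 1) = m1;
      traj(row, 2) = m2;
      traj(row, 3) = den > 0 ? std::fabs((c1 - c2) / den) : NA_REAL;
      traj(row, 4) = (double)mo.cells.size();
      ++row;
      if (t == nsteps) break;
    }
  }
  IntegerVector cellOut(n);
  for (int i = 0; i < n; ++i) cellOut[i] = mo.cellOf[i] + 1;
  return List::create(_["traj"] = traj(Range(0, row - 1), _),
                      _["k1"] = NumericVector(mo.k1.begin(), mo.k1.end()),
                      _["k2"] = NumericVector(mo.k2.begin(), mo.k2.end()),
                      _["cell"] = cellOut);
}
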