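// Individual-based protocell engine: two-step replication (complex formation,
// replication, decay) inside dividing compartments, with exact conservation of
// the total particle number N. All randomness goes through R's RNG so that
// set.seed() gives exact replay.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

// mutation methods
const int MUT_ADDITIVE_FREE = 1;   // additive, no lower bound (k < 0 kept)
const int MUT_ADDITIVE_REFLECT0 = 2; // additive, reflecting at 0
const int MUT_MULT_LOG = 3;        // multiplicative (random walk in log scale)

// symmetry modes
const int SYM_NONE = 0;
const int SYM_KINETIC = 1;    // k_PP = k_PM, k_MP = k_MM
const int SYM_FUNCTIONAL = 2; // k_PP = k_MP, k_PM = k_MM
const int SYM_BOTH = 3;

// model variants
const int VAR_TWO_STEP = 0;
const int VAR_ONE_STEP = 1;
const int VAR_CROSS_CHIRAL = 2;

struct Params {
  int V;
  long long N;
  double m, delta, d;
  double k_upper;          // R_PosInf => unbounded above
  int mutation_method;
  int symmetry_mode;
  int variant;
  bool mutate_all;         // mutate all tied groups per mutation event
  bool split_complex_units;// complexes partition as a unit at division
};

Params paramsFromList(const List& p) {
  Params q;
  q.V = as<int>(p["V"]);
  q.N = (long long) as<double>(p["N"]);
  q.m = as<double>(p["m"]);
  q.delta = as<double>(p["delta"]);
  q.d = as<double>(p["d"]);
  q.k_upper = as<double>(p["k_upper"]);
  q.mutation_method = as<int>(p["mutation_method_code"]);
  q.symmetry_mode = as<int>(p["symmetry_mode_code"]);
  q.variant = as<int>(p["variant_code"]);
  q.mutate_all = as<bool>(p["mutate_all"]);
  q.split_complex_units = as<bool>(p["split_complex_units"]);
  return q;
}

inline int randInt(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

inline double effRate(double k) { return k > 0.0 ? k : 0.0; }

// reflect val into (-inf, up] (additive walks); lower bound at 0 optional
inline double reflectUpper(double val, double up) {
  if (R_FINITE(up)) while (val > up) val = 2.0 * up - val;
  return val;
}

// One mutation event: perturb the k vector in place, respecting the symmetry
// ties and the boundary conventions of the chosen method. Tied groups are
// perturbed by the mean of as many independent draws as there are members, so
// the variance generated in sum(k) is identical to the unconstrained model.
void mutateK(double k[4], const Params& p) {
  // index layout: 0 = PP, 1 = PM, 2 = MP, 3 = MM
  static const int groupsNone[4][4] = {{0,-1,-1,-1},{1,-1,-1,-1},{2,-1,-1,-1},{3,-1,-1,-1}};
  static const int groupsKin[2][4]  = {{0,1,-1,-1},{2,3,-1,-1}};
  static const int groupsFun[2][4]  = {{0,2,-1,-1},{1,3,-1,-1}};
  static const int groupsBoth[1][4] = {{0,1,2,3}};
  const int (*groups)[4]; int ngroups;
  switch (p.symmetry_mode) {
  case SYM_KINETIC:    groups = groupsKin;  ngroups = 2; break;
  case SYM_FUNCTIONAL: groups = groupsFun;  ngroups = 2; break;
  case SYM_BOTH:       groups = groupsBoth; ngroups = 1; break;
  default:             groups = groupsNone; ngroups = 4; break;
  }
  int gFirst = 0, gLast = ngroups - 1;
  if (!p.mutate_all) gFirst = gLast = randInt(ngroups);
  for (int g = gFirst; g <= gLast; ++g) {
    int size = 0;
    while (size < 4 && groups[g][size] >= 0) ++size;
    if (p.mutation_method == MUT_MULT_LOG) {
      double lf = 0.0;
      for (int i = 0; i < size; ++i)
        lf += std::log(1.0 - p.delta + 2.0 * p.delta * unif_rand());
      double f = std::exp(lf / size);
      for (int i = 0; i < size; ++i) {
        int j = groups[g][i];
        double v = k[j] * f;
        // reflect in log scale at the upper bound (for positive k)
        if (R_FINITE(p.k_upper) && v > p.k_upper) v = p.k_upper * p.k_upper / v;
        k[j] = v;
      }
    } else {
      double eps = 0.0;
      for (int i = 0; i < size; ++i)
        eps += (-p.delta + 2.0 * p.delta * unif_rand());
      eps /= size;
      for (int i = 0; i < size; ++i) {
        int j = groups[g][i];
        double v = k[j] + eps;
        v = reflectUpper(v, p.k_upper);
        if (p.mutation_method == MUT_ADDITIVE_REFLECT0) {
          while (v < 0.0) {
            v = -v;
            v = reflectUpper(v, p.k_upper);
          }
        }
        k[j] = v;
      }
    }
  }
}

struct Rep {
  int cell;     // cell index
  int strand;   // 0 = P, 1 = M
  int chir;     // 0 = L, 1 = D (cross-chiral variant only)
  double k[4];  // k_PP, k_PM, k_MP, k_MM
  int partner;  // arena index of complex partner, -1 if free
  bool tmpl;    // this member serves as template in its complex
  int pos;      // position within its cell's member list
};

struct Sim {
  Params p;
  std::vector<Rep> reps;       // arena
  std::vector<int> freeIdx;    // recycled arena slots
  std::vector<std::vector<int> > members; // replicator indices per cell
  std::vector<long long> nsub; // substrate count per cell
  long long nRepTotal;
  bool extinct;
  long long step;

  int ncells() const { return (int)members.size(); }

  long long cellTotal(int c) const { return (long long)members[c].size() + nsub[c]; }

  int newRep(int cell, int strand, int chir, const double kk[4]) {
    int idx;
    if (!freeIdx.empty()) { idx = freeIdx.back(); freeIdx.pop_back(); }
    else { reps.push_back(Rep()); idx = (int)reps.size() - 1; }
    Rep& r = reps[idx];
    r.cell = cell; r.strand = strand; r.chir = chir;
    std::memcpy(r.k, kk, 4 * sizeof(double));
    r.partner = -1; r.tmpl = false;
    r.pos = (int)members[cell].size();
    members[cell].push_back(idx);
    ++nRepTotal;
    return idx;
  }

  void removeRepFromCell(int idx) {
    Rep& r = reps[idx];
    std::vector<int>& mem = members[r.cell];
    int last = mem.back();
    mem[r.pos] = last;
    reps[last].pos = r.pos;
    mem.pop_back();
  }

  void dissociate(int idx) {
    int j = reps[idx].partner;
    if (j >= 0) {
      reps[j].partner = -1; reps[j].tmpl = false;
      reps[idx].partner = -1; reps[idx].tmpl = false;
    }
  }

  // replicator -> substrate, same cell
  void decay(int idx) {
    dissociate(idx);
    removeRepFromCell(idx);
    nsub[reps[idx].cell] += 1;
    freeIdx.push_back(idx);
    --nRepTotal;
  }

  // consume one substrate of cell `c`; new replicator complementary to tmplIdx
  void replicate(int c, int tmplIdx) {
    nsub[c] -= 1;
    const Rep& t = reps[tmplIdx];
    double kk[4];
    std::memcpy(kk, t.k, 4 * sizeof(double));
    if (unif_rand() < p.m) mutateK(kk, p);
    newRep(c, 1 - t.strand, t.chir, kk);
  }

  double maxEffectiveRate() const {
    double mx = 0.0;
    for (int c = 0; c < ncells(); ++c)
      for (size_t i = 0; i < members[c].size(); ++i) {
        const Rep& r = reps[members[c][i]];
        for (int j = 0; j < 4; ++j) if (r.k[j] > mx) mx = r.k[j];
      }
    return mx;
  }

  double alphaNow() const {
    double kmax = R_FINITE(p.k_upper) ? p.k_upper : maxEffectiveRate();
    return 1.0 / (kmax + 0.25 + p.d);
  }

  // Complex-formation rate of catalyst X towards template Y (strand-indexed;
  // in the cross-chiral variant catalysis requires opposite chirality).
  double rateCat(const Rep& X, const Rep& Y) const {
    if (p.variant == VAR_CROSS_CHIRAL && X.chir == Y.chir) return 0.0;
    return effRate(X.k[X.strand * 2 + Y.strand]);
  }

  // One micro-iteration of the reaction algorithm. `cum` is the per-cell
  // cumulative particle-count table (cell totals are invariant within a
  // reaction step: replication and decay swap a replicator for a substrate).
  // Returns an event code (0 none, 1 complex, 2 replication, 3 decay).
  int microIteration(const std::vector<double>& cum, double alpha) {
    const double ab = alpha * 0.5;   // alpha * beta
    const double ag = alpha * 0.25;  // alpha * gamma
    const double ad = alpha * p.d;
    // pick X uniformly among all N particles: cell by cumulative counts
    double u = unif_rand() * cum.back();
    int c = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (c >= ncells()) c = ncells() - 1;
    long long tot = cellTotal(c);
    if (tot <= 0) return 0;
    int nrep = (int)members[c].size();
    int slotX = (int)(unif_rand() * tot);
    if (slotX >= tot) slotX = (int)tot - 1;
    bool xIsRep = slotX < nrep;
    int X = xIsRep ? members[c][slotX] : -1;

    if (!xIsRep) {
      // X is a substrate: only replication (with a complexed Y) can involve it
      if (tot < 2) return 0;
      int slotY;
      do { slotY = (int)(unif_rand() * tot); if (slotY >= tot) slotY = (int)tot - 1; }
      while (slotY == slotX);
      if (slotY < nrep) {
        int Y = members[c][slotY];
        if (reps[Y].partner >= 0 && p.variant != VAR_ONE_STEP) {
          if (unif_rand() < ag) {
            int t = reps[Y].tmpl ? Y : reps[Y].partner;
            int cat = reps[t].partner;
            dissociate(t);
            replicate(c, t);
            (void)cat;
            return 2;
          }
        }
      }
      return 0;
    }

    // X is a replicator
    int partnerX = reps[X].partner;
    int slotPartner = -1;
    if (partnerX >= 0) slotPartner = reps[partnerX].pos;
    long long eligible = tot - 1 - (partnerX >= 0 ? 1 : 0);
    if (eligible <= 0) {
      // no eligible Y: only decay of X is attempted
      if (unif_rand() < ad) { decay(X); return 3; }
      return 0;
    }
    int slotY;
    do { slotY = (int)(unif_rand() * tot); if (slotY >= tot) slotY = (int)tot - 1; }
    while (slotY == slotX || slotY == slotPartner);
    bool yIsRep = slotY < nrep;
    double uu = unif_rand();

    if (yIsRep) {
      int Y = members[c][slotY];
      bool xFree = partnerX < 0, yFree = reps[Y].partner < 0;
      if (xFree && yFree) {
        double pX = ab * rateCat(reps[X], reps[Y]);
        double pY = ab * rateCat(reps[Y], reps[X]);
        if (p.variant == VAR_ONE_STEP) {
          // instantaneous replication: a catalyst-template encounter converts
          // one substrate of the cell into the template's complement
          if (uu < pX) {
            if (nsub[c] > 0) { replicate(c, Y); return 2; }
            return 0;
          } else if (uu < pX + pY) {
            if (nsub[c] > 0) { replicate(c, X); return 2; }
            return 0;
          } else if (uu < pX + pY + ad) { decay(X); return 3; }
          return 0;
        }
        if (uu < pX) { // X catalyst, Y template
          reps[X].partner = Y; reps[Y].partner = X;
          reps[X].tmpl = false; reps[Y].tmpl = true;
          return 1;
        } else if (uu < pX + pY) { // Y catalyst, X template
          reps[X].partner = Y; reps[Y].partner = X;
          reps[Y].tmpl = false; reps[X].tmpl = true;
          return 1;
        } else if (uu < pX + pY + ad) { decay(X); return 3; }
        return 0;
      }
      // complexed/incompatible pairing: only X's decay remains possible
      if (uu < ad) { decay(X); return 3; }
      return 0;
    }
    // Y is a substrate
    if (partnerX >= 0 && p.variant != VAR_ONE_STEP) {
      if (uu < ag) {
        int t = reps[X].tmpl ? X : partnerX;
        dissociate(t);
        replicate(c, t);
        return 2;
      } else if (uu < ag + ad) { decay(X); return 3; }
      return 0;
    }
    if (uu < ad) { decay(X); return 3; }
    return 0;
  }

  void buildCum(std::vector<double>& cum) const {
    cum.resize(ncells());
    double acc = 0.0;
    for (int c = 0; c < ncells(); ++c) { acc += (double)cellTotal(c); cum[c] = acc; }
  }

  // One reaction step: N/alpha micro-iterations (fractional part carried
  // stochastically so the expected iteration count is exact).
  void reactionStep() {
    if (nRepTotal == 0) { extinct = true; return; }
    double alpha = alphaNow();
    long long Ntot = 0;
    for (int c = 0; c < ncells(); ++c) Ntot += cellTotal(c);
    double niterf = (double)Ntot / alpha;
    long long niter = (long long)niterf;
    if (unif_rand() < niterf - (double)niter) ++niter;
    std::vector<double> cum;
    buildCum(cum);
    for (long long i = 0; i < niter; ++i) microIteration(cum, alpha);
    if (nRepTotal == 0) extinct = true;
  }

  // Substrates are pooled and redistributed multinomially with weights equal
  // to the replicator count of each cell (sequential conditional binomials).
  void diffusionStep() {
    long long S = 0;
    double wsum = 0.0;
    for (int c = 0; c < ncells(); ++c) { S += nsub[c]; wsum += (double)members[c].size(); }
    if (wsum <= 0.0) { extinct = true; return; }
    long long rem = S;
    for (int c = 0; c < ncells(); ++c) {
      double w = (double)members[c].size();
      long long x = 0;
      if (rem > 0 && w > 0.0) {
        if (wsum - w <= 0.0) x = rem;
        else x = (long long) R::rbinom((double)rem, w / wsum);
      }
      nsub[c] = x;
      rem -= x;
      wsum -= w;
    }
  }

  void moveRepToCell(int idx, int to) {
    removeRepFromCell(idx);
    reps[idx].cell = to;
    reps[idx].pos = (int)members[to].size();
    members[to].push_back(idx);
  }

  // Every cell with >= V particles is split; each particle goes to either
  // daughter with probability 1/2, complexes as a unit (configurable).
  // Cells left with zero particles are removed.
  void divisionStep() {
    bool any = true;
    while (any) {
      any = false;
      // complexes decided once per pass, marked by arena id
      std::vector<char> pairDone(reps.size(), 0);
      int nc = ncells();
      for (int c = 0; c < nc; ++c) {
        if (cellTotal(c) < p.V) continue;
        any = true;
        members.push_back(std::vector<int>());
        nsub.push_back(0);
        int d = ncells() - 1;
        if (!p.split_complex_units) {
          std::vector<int> snap = members[c];
          for (size_t i = 0; i < snap.size(); ++i) dissociate(snap[i]);
        }
        std::vector<int> snap = members[c];
        for (size_t i = 0; i < snap.size(); ++i) {
          int idx = snap[i];
          int pr = reps[idx].partner;
          if (pr >= 0) {
            // decide once per complex, at its first-encountered member
            if (pairDone[idx]) continue;
            pairDone[idx] = pairDone[pr] = 1;
            if (unif_rand() < 0.5) { moveRepToCell(idx, d); moveRepToCell(pr, d); }
          } else {
            if (unif_rand() < 0.5) moveRepToCell(idx, d);
          }
        }
        long long smove = (long long) R::rbinom((double)nsub[c], 0.5);
        nsub[c] -= smove;
        nsub[d] += smove;
      }
    }
    // drop empty cells
    int w = 0;
    std::vector<int> newIdx(ncells(), -1);
    for (int c = 0; c < ncells(); ++c) {
      if (cellTotal(c) > 0) { newIdx[c] = w; ++w; }
    }
    if (w != ncells()) {
      std::vector<std::vector<int> > mem2(w);
      std::vector<long long> sub2(w);
      for (int c = 0; c < ncells(); ++c) {
        if (newIdx[c] < 0) continue;
        mem2[newIdx[c]].swap(members[c]);
        sub2[newIdx[c]] = nsub[c];
      }
      members.swap(mem2);
      nsub.swap(sub2);
      for (int c = 0; c < ncells(); ++c)
        for (size_t i = 0; i < members[c].size(); ++i)
          reps[members[c][i]].cell = c;
    }
  }
};

Sim simFromState(const List& state) {
  Sim s;
  s.p = paramsFromList(state["cparams"]);
  DataFrame rd = as<DataFrame>(state["replicators"]);
  IntegerVector cell = rd["cell"];
  IntegerVector strand = rd["strand_code"];
  IntegerVector chir = rd["chirality_code"];
  NumericVector kPP = rd["kPP"], kPM = rd["kPM"], kMP = rd["kMP"], kMM = rd["kMM"];
  IntegerVector partner = rd["partner"];
  LogicalVector tmpl = rd["is_template"];
  IntegerVector sub = state["substrates"];
  int nc = sub.size();
  s.members.resize(nc);
  s.nsub.resize(nc);
  for (int c = 0; c < nc; ++c) s.nsub[c] = sub[c];
  int n = rd.nrows();
  s.reps.resize(n);
  s.nRepTotal = n;
  for (int i = 0; i < n; ++i) {
    Rep& r = s.reps[i];
    r.cell = cell[i] - 1;
    r.strand = strand[i];
    r.chir = chir[i];
    r.k[0] = kPP[i]; r.k[1] = kPM[i]; r.k[2] = kMP[i]; r.k[3] = kMM[i];
    r.partner = (partner[i] == NA_INTEGER) ? -1 : partner[i] - 1;
    r.tmpl = tmpl[i] == TRUE;
    r.pos = (int)s.members[r.cell].size();
    s.members[r.cell].push_back(i);
  }
  s.extinct = as<bool>(state["extinct"]);
  s.step = (long long) as<double>(state["step"]);
  return s;
}

List simToState(const Sim& s, const List& stateTemplate) {
  // compact arena to live replicators only
  std::vector<int> live;
  std::vector<int> newIdx(s.reps.size(), -1);
  for (int c = 0; c < s.ncells(); ++c)
    for (size_t i = 0; i < s.members[c].size(); ++i) {
      newIdx[s.members[c][i]] = (int)live.size();
      live.push_back(s.members[c][i]);
    }
  int n = (int)live.size();
  IntegerVector cell(n), strand(n), chir(n), partner(n);
  NumericVector kPP(n), kPM(n), kMP(n), kMM(n);
  LogicalVector tmpl(n);
  for (int i = 0; i < n; ++i) {
    const Rep& r = s.reps[live[i]];
    cell[i] = r.cell + 1;
    strand[i] = r.strand;
    chir[i] = r.chir;
    kPP[i] = r.k[0]; kPM[i] = r.k[1]; kMP[i] = r.k[2]; kMM[i] = r.k[3];
    partner[i] = (r.partner < 0) ? NA_INTEGER : newIdx[r.partner] + 1;
    tmpl[i] = r.tmpl;
  }
  DataFrame rd = DataFrame::create(
    _["cell"] = cell, _["strand_code"] = strand, _["chirality_code"] = chir,
    _["kPP"] = kPP, _["kPM"] = kPM, _["kMP"] = kMP, _["kMM"] = kMM,
    _["partner"] = partner, _["is_template"] = tmpl);
  IntegerVector sub(s.ncells());
  for (int c = 0; c < s.ncells(); ++c) sub[c] = (int)s.nsub[c];
  List out = clone(stateTemplate);
  out["replicators"] = rd;
  out["substrates"] = sub;
  out["extinct"] = s.extinct;
  out["step"] = (double)s.step;
  return out;
}

void recordRow(const Sim& s, NumericMatrix& traj, int row) {
  long long nP = 0, nM = 0, S = 0;
  double sum[4] = {0,0,0,0}, sq[4] = {0,0,0,0};
  for (int c = 0; c < s.ncells(); ++c) {
    S += s.nsub[c];
    for (size_t i = 0; i < s.members[c].size(); ++i) {
      const Rep& r = s.reps[s.members[c][i]];
      if (r.strand == 0) ++nP; else ++nM;
      for (int j = 0; j < 4; ++j) { sum[j] += r.k[j]; sq[j] += r.k[j] * r.k[j]; }
    }
  }
  double n = (double)(nP + nM);
  traj(row, 0) = (double)s.step;
  traj(row, 1) = (double)s.ncells();
  traj(row, 2) = (double)nP;
  traj(row, 3) = (double)nM;
  traj(row, 4) = (double)S;
  for (int j = 0; j < 4; ++j) {
    double mu = n > 0 ? sum[j] / n : NA_REAL;
    double v  = n > 1 ? (sq[j] - n * mu * mu) / (n - 1.0) : NA_REAL;
    traj(row, 5 + j) = mu;
    traj(row, 9 + j) = (n > 1 && v > 0) ? std::sqrt(v) : (n > 1 ? 0.0 : NA_REAL);
  }
}

} // namespace

// [[Rcpp::export]]
List cppReactionStep(List state, int nsteps) {
  Sim s = simFromState(state);
  for (int i = 0; i < nsteps && !s.extinct; ++i) { s.reactionStep(); ++s.step; }
  return simToState(s, state);
}

// [[Rcpp::export]]
List cppDiffusionStep(List state) {
  Sim s = simFromState(state);
  s.diffusionStep();
  return simToState(s, state);
}

// [[Rcpp::export]]
List cppDivisionStep(List state) {
  Sim s = simFromState(state);
  s.divisionStep();
  return simToState(s, state);
}

// [[Rcpp::export]]
List cppRunSimulation(List state, double steps, double stride) {
  Sim s = simFromState(state);
  long long nsteps = (long long)steps, str = (long long)stride;
  if (str < 1) str = 1;
  int nrow = (int)(nsteps / str) + 2;
  NumericMatrix traj(nrow, 13);
  int row = 0;
  recordRow(s, traj, row++);
  long long done = 0;
  for (long long t = 1; t <= nsteps; ++t) {
    s.reactionStep();
    if (!s.extinct) s.diffusionStep();
    if (!s.extinct) s.divisionStep();
    ++s.step;
    done = t;
    if (s.extinct) break;
    if (t % str == 0 && row < nrow - 1) recordRow(s, traj, row++);
  }
  if (s.extinct || done % str != 0) recordRow(s, traj, row++);
  return List::create(_["traj"] = traj(Range(0, row - 1), _),
                      _["state"] = simToState(s, state),
                      _["extinct"] = s.extinct,
                      _["steps_run"] = (double)done);
}

// Run micro-iterations from a frozen state until the first state-changing
// event; repeat ntrials times from the same state. Used to compare the
// discrete reaction algorithm against an exact continuous-time (Gillespie)
// description of the same network.
// [[Rcpp::export]]
DataFrame cppFirstEvents(List state, int ntrials) {
  Sim s0 = simFromState(state);
  IntegerVector type(ntrials);
  NumericVector iters(ntrials);
  for (int t = 0; t < ntrials; ++t) {
    Sim s = s0;
    double alpha = s.alphaNow();
    std::vector<double> cum;
    s.buildCum(cum);
    long long it = 0;
    int ev = 0;
    while (ev == 0) {
      ++it;
      ev = s.microIteration(cum, alpha);
      if (it > 100000000LL) break;
    }
    type[t] = ev;
    iters[t] = (double)it;
  }
  return DataFrame::create(_["type"] = type, _["iterations"] = iters);
}

// Single-lineage assay: one protocell against an infinite background
// population. Diffusion sets the substrate count to a Poisson draw with mean
// n_R * bg_ratio (bg_ratio = N'_S / N'_R); at division one daughter is kept at
// random. Runs until the lineage dies (no replicators) or max_steps.
// [[Rcpp::export]]
List cppRunLineage(List state, double bg_ratio, double restoration_fraction,
                   double max_steps) {
  Sim s = simFromState(state);
  long long divisions = 0, restorations = 0;
  long long minPart = s.cellTotal(0), minRep = (long long)s.members[0].size();
  bool below = false, restored = false, died = false;
  long long maxSteps = (long long)max_steps;
  double thr = restoration_fraction * (double)s.p.V;
  for (long long t = 0; t < maxSteps; ++t) {
    s.reactionStep();
    if (s.nRepTotal == 0) { died = true; break; }
    // diffusion against the infinite background
    long long nr = (long long)s.members[0].size();
    s.nsub[0] = (long long) R::rpois((double)nr * bg_ratio);
    // division: keep one daughter
    if (s.cellTotal(0) >= s.p.V) {
      ++divisions;
      if (below) { restored = true; ++restorations; }
      // the kept daughter is the set of particles surviving the binomial
      // split; discarding the other daughter removes its particles outright
      std::vector<int> snap = s.members[0];
      std::vector<char> pairDone(s.reps.size(), 0);
      for (size_t i = 0; i < snap.size(); ++i) {
        int idx = snap[i];
        int pr = s.reps[idx].partner;
        if (pr >= 0 && !s.p.split_complex_units) {
          s.dissociate(idx);
          pr = -1;
        }
        if (pr >= 0) {
          if (pairDone[idx]) continue;
          pairDone[idx] = pairDone[pr] = 1;
          if (unif_rand() < 0.5) { // both members go with the lost daughter
            s.dissociate(idx);
            s.removeRepFromCell(idx); s.freeIdx.push_back(idx); --s.nRepTotal;
            s.removeRepFromCell(pr); s.freeIdx.push_back(pr); --s.nRepTotal;
          }
        } else {
          if (unif_rand() < 0.5) {
            s.removeRepFromCell(idx); s.freeIdx.push_back(idx); --s.nRepTotal;
          }
        }
      }
      s.nsub[0] = (long long) R::rbinom((double)s.nsub[0], 0.5);
      if (s.nRepTotal == 0) { died = true; break; }
    }
    long long tot = s.cellTotal(0);
    long long nrep2 = (long long)s.members[0].size();
    if (tot < minPart) minPart = tot;
    if (nrep2 < minRep) minRep = nrep2;
    if ((double)tot < thr) below = true;
    ++s.step;
  }
  return List::create(_["divisions"] = (double)divisions,
                      _["restorations"] = (double)restorations,
                      _["restored"] = restored,
                      _["min_particles"] = (double)minPart,
                      _["min_replicators"] = (double)minRep,
                      _["extinct"] = died,
                      _["steps"] = (double)s.step);
}

// Pilot measurement for initial-k calibration: a single closed cell (no
// diffusion, no division, mutation off), returning the time-averaged
// replicator density n_R / (n_R + n_S) after burn-in.
// [[Rcpp::export]]
double cppClosedCellDensity(List state, double steps, double burnin) {
  Sim s = simFromState(state);
  long long nsteps = (long long)steps, nburn = (long long)burnin;
  double acc = 0.0;
  long long nacc = 0;
  for (long long t = 0; t < nsteps; ++t) {
    s.reactionStep();
    if (s.nRepTotal == 0) return 0.0;
    if (t >= nburn) {
      double tot = (double)s.cellTotal(0);
      acc += (double)s.members[0].size() / tot;
      ++nacc;
    }
  }
  return nacc > 0 ? acc / (double)nacc : 0.0;
}
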