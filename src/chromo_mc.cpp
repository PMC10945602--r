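// Mesoscale chromatin energy model and Metropolis Monte Carlo kernel.
//
// The R side builds a flat "bead model" (site table, bonded terms, force-field
// scalars) from a FiberTopology + ForceField; everything here operates on that
// flat representation. All indices arriving from R are 1-based and converted
// on load. Harmonic terms use the E = k (x - x0)^2 convention (no 1/2 factor).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <random>
#include <limits>

using namespace Rcpp;

static const int NCOMP = 10; // ES EB ET EtS EtB ElhS ElhB EV EC ETF

// ---------------------------------------------------------------------------
// Deterministic RNG (xorshift-free; mt19937_64 with manual double conversion
// so streams are identical across platforms/compilers).
// ---------------------------------------------------------------------------
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { // [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double unifSym() { return 2.0 * unif() - 1.0; } // (-1, 1)
  void unitBall(double* v) {
    double r2;
    do {
      v[0] = unifSym(); v[1] = unifSym(); v[2] = unifSym();
      r2 = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
    } while (r2 > 1.0 || r2 < 1e-12);
  }
  void unitVec(double* v) {
    unitBall(v);
    double n = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    v[0] /= n; v[1] /= n; v[2] /= n;
  }
  int sampleInt(int n) { // 0..n-1
    return (int)std::floor(unif() * n);
  }
};

static inline double dist3(const double* a, const double* b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}
static inline double dist2of(const double* a, const double* b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return dx*dx + dy*dy + dz*dz;
}

// Rotation matrix (row-major 3x3) about unit axis u by angle th (Rodrigues).
static void rotMat(const double* u, double th, double* R) {
  double c = std::cos(th), s = std::sin(th), C = 1.0 - c;
  R[0] = c + u[0]*u[0]*C;      R[1] = u[0]*u[1]*C - u[2]*s; R[2] = u[0]*u[2]*C + u[1]*s;
  R[3] = u[1]*u[0]*C + u[2]*s; R[4] = c + u[1]*u[1]*C;      R[5] = u[1]*u[2]*C - u[0]*s;
  R[6] = u[2]*u[0]*C - u[1]*s; R[7] = u[2]*u[1]*C + u[0]*s; R[8] = c + u[2]*u[2]*C;
}
static inline void applyRot(const double* R, const double* v, double* out) {
  out[0] = R[0]*v[0] + R[1]*v[1] + R[2]*v[2];
  out[1] = R[3]*v[0] + R[4]*v[1] + R[5]*v[2];
  out[2] = R[6]*v[0] + R[7]*v[1] + R[8]*v[2];
}

// ---------------------------------------------------------------------------
// Model
// ---------------------------------------------------------------------------
struct Model {
  int N = 0, nC = 0, nRuns = 0;
  std::vector<int> type;         // 0 linker, 1 core, 2 surface charge, 3 tail, 4 lh, 5 attachment
  std::vector<int> parent;       // owning core (0-based) or -1 (linker beads)
  std::vector<int> group;        // spatial group = nearest core (0..nC-1), all sites
  std::vector<int> chainPos;     // order along the fiber chain (cores + linker beads; children = core's)
  std::vector<int> linkerIndex;  // 1..M for linker beads along the chain, -1 otherwise
  std::vector<double> charge, radius;
  std::vector<char> interacting; // participates in nonbonded terms
  std::vector<char> bindable;    // TF-bindable linker bead
  // bonds
  std::vector<int> bI, bJ, bCls, bCore; // bCls: 0 DNA, 1 tail, 2 LH; bCore: tail core or -1
  std::vector<double> bK, bL0w, bL0f;
  // angles, vertex j
  std::vector<int> aI, aJ, aK, aCls;
  std::vector<double> aG, aTh0;
  std::vector<std::vector<int>> siteBonds, siteAngles;
  std::vector<std::vector<int>> children; // per core: all sites with parent == core
  std::vector<int> coreSite;              // site index of each core centre
  std::vector<std::vector<int>> tails;    // per tail chain: bead sites in order
  std::vector<int> tailAttach, tailCore;
  double twistS = 0.0;
  std::vector<double> twistEq; // radians, per run
  double kev = 0, kc = 0, lambda = 1, rcut = 12, kBT = 1;
  std::vector<int64_t> excl;   // sorted encoded bonded pairs
  std::vector<int> inter;      // list of interacting sites
  std::vector<int> linkerSites, lhSites, bindableSites;

  bool bondedExcl(int i, int j) const {
    int64_t key = (i < j) ? (int64_t)i * N + j : (int64_t)j * N + i;
    return std::binary_search(excl.begin(), excl.end(), key);
  }
  bool excluded(int i, int j) const {
    if (parent[i] >= 0 && parent[i] == parent[j]) return true;
    return bondedExcl(i, j);
  }
  double bondL0(int b, const int* folded) const {
    if (bCore[b] >= 0 && folded[bCore[b]]) return bL0f[b];
    return bL0w[b];
  }
};

static Model loadModel(const List& m) {
  Model M;
  M.N = as<int>(m["nSites"]);
  M.nC = as<int>(m["nCores"]);
  M.nRuns = as<int>(m["nRuns"]);
  IntegerVector type = m["type"], parent = m["parent"], group = m["group"],
    chainPos = m["chainPos"], linkerIndex = m["linkerIndex"];
  NumericVector charge = m["charge"], radius = m["radius"];
  LogicalVector interacting = m["interacting"], bindable = m["bindable"];
  M.type.assign(type.begin(), type.end());
  M.parent.resize(M.N); M.group.resize(M.N);
  M.chainPos.assign(chainPos.begin(), chainPos.end());
  M.linkerIndex.resize(M.N);
  for (int i = 0; i < M.N; ++i) {
    M.parent[i] = parent[i] == NA_INTEGER ? -1 : parent[i] - 1;
    M.group[i] = group[i] - 1;
    M.linkerIndex[i] = linkerIndex[i] == NA_INTEGER ? -1 : linkerIndex[i];
  }
  M.charge.assign(charge.begin(), charge.end());
  M.radius.assign(radius.begin(), radius.end());
  M.interacting.resize(M.N); M.bindable.resize(M.N);
  for (int i = 0; i < M.N; ++i) {
    M.interacting[i] = interacting[i] ? 1 : 0;
    M.bindable[i] = bindable[i] ? 1 : 0;
    if (M.interacting[i]) M.inter.push_back(i);
    if (M.type[i] == 0) M.linkerSites.push_back(i);
    if (M.type[i] == 4) M.lhSites.push_back(i);
    if (M.bindable[i]) M.bindableSites.push_back(i);
  }
  List bonds = m["bonds"];
  IntegerVector bi = bonds["i"], bj = bonds["j"], bcls = bonds["cls"], bcore = bonds["core"];
  NumericVector bk = bonds["k"], bl0w = bonds["l0"], bl0f = bonds["l0folded"];
  int nB = bi.size();
  for (int b = 0; b < nB; ++b) {
    M.bI.push_back(bi[b] - 1); M.bJ.push_back(bj[b] - 1);
    M.bCls.push_back(bcls[b]);
    M.bCore.push_back(bcore[b] == NA_INTEGER ? -1 : bcore[b] - 1);
    M.bK.push_back(bk[b]); M.bL0w.push_back(bl0w[b]); M.bL0f.push_back(bl0f[b]);
  }
  List angles = m["angles"];
  IntegerVector ai = angles["i"], aj = angles["j"], ak = angles["k"], acls = angles["cls"];
  NumericVector ag = angles["g"], ath0 = angles["theta0"];
  int nA = ai.size();
  for (int a = 0; a < nA; ++a) {
    M.aI.push_back(ai[a] - 1); M.aJ.push_back(aj[a] - 1); M.aK.push_back(ak[a] - 1);
    M.aCls.push_back(acls[a]); M.aG.push_back(ag[a]); M.aTh0.push_back(ath0[a]);
  }
  M.siteBonds.assign(M.N, {});
  M.siteAngles.assign(M.N, {});
  for (int b = 0; b < nB; ++b) {
    M.siteBonds[M.bI[b]].push_back(b);
    M.siteBonds[M.bJ[b]].push_back(b);
  }
  for (int a = 0; a < nA; ++a) {
    M.siteAngles[M.aI[a]].push_back(a);
    M.siteAngles[M.aJ[a]].push_back(a);
    M.siteAngles[M.aK[a]].push_back(a);
  }
  M.children.assign(M.nC, {});
  for (int i = 0; i < M.N; ++i)
    if (M.parent[i] >= 0) M.children[M.parent[i]].push_back(i);
  IntegerVector coreSite = m["coreSite"];
  for (int c = 0; c < M.nC; ++c) M.coreSite.push_back(coreSite[c] - 1);
  List tails = m["tails"];
  IntegerVector tAtt = m["tailAttach"], tCore = m["tailCore"];
  for (int t = 0; t < tails.size(); ++t) {
    IntegerVector tb = tails[t];
    std::vector<int> v;
    for (int i = 0; i < tb.size(); ++i) v.push_back(tb[i] - 1);
    M.tails.push_back(v);
    M.tailAttach.push_back(tAtt[t] - 1);
    M.tailCore.push_back(tCore[t] - 1);
  }
  M.twistS = as<double>(m["twistS"]);
  NumericVector teq = m["twistEq"];
  M.twistEq.assign(teq.begin(), teq.end());
  M.kev = as<double>(m["kev"]);
  M.kc = as<double>(m["kc"]);
  M.lambda = as<double>(m["debyeLength"]);
  M.rcut = as<double>(m["rcut"]);
  M.kBT = as<double>(m["kBT"]);
  for (int b = 0; b < nB; ++b) {
    int i = M.bI[b], j = M.bJ[b];
    int64_t key = (i < j) ? (int64_t)i * M.N + j : (int64_t)j * M.N + i;
    M.excl.push_back(key);
  }
  std::sort(M.excl.begin(), M.excl.end());
  M.excl.erase(std::unique(M.excl.begin(), M.excl.end()), M.excl.end());
  return M;
}

// ---------------------------------------------------------------------------
// Energy terms
// ---------------------------------------------------------------------------
static inline double bondEnergyB(const Model& M, int b, const double* X, const int* folded) {
  const double* pi = X + 3 * M.bI[b];
  const double* pj = X + 3 * M.bJ[b];
  double d = dist3(pi, pj) - M.bondL0(b, folded);
  return M.bK[b] * d * d;
}

// deviation-from-straight angle at vertex j: theta = pi - angle(i-j, k-j)
static inline double bendTheta(const double* pi, const double* pj, const double* pk) {
  double u[3] = { pi[0]-pj[0], pi[1]-pj[1], pi[2]-pj[2] };
  double v[3] = { pk[0]-pj[0], pk[1]-pj[1], pk[2]-pj[2] };
  double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
  double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
  if (nu < 1e-12 || nv < 1e-12) return 0.0;
  double c = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu*nv);
  c = std::max(-1.0, std::min(1.0, c));
  return M_PI - std::acos(c);
}
static inline double angleEnergyA(const Model& M, int a, const double* X) {
  double th = bendTheta(X + 3*M.aI[a], X + 3*M.aJ[a], X + 3*M.aK[a]);
  double d = th - M.aTh0[a];
  return M.aG[a] * d * d;
}

// nonbonded pair energy (cutoff first, then exclusions); adds into ev/ec
static inline void pairEnergy(const Model& M, int i, int j, const double* X,
                              double& ev, double& ec) {
  double r2 = dist2of(X + 3*i, X + 3*j);
  if (r2 > M.rcut * M.rcut) return;
  if (M.excluded(i, j)) return;
  double r = std::sqrt(r2);
  if (M.radius[i] > 0 && M.radius[j] > 0) {
    double sig = M.radius[i] + M.radius[j];
    if (r < sig) {
      double s6 = sig*sig / std::max(r2, 1e-12); s6 = s6 * s6 * s6;
      ev += M.kev * (s6 * s6 - 2.0 * s6 + 1.0);
    }
  }
  double qq = M.charge[i] * M.charge[j];
  if (qq != 0.0 && r > 1e-9)
    ec += M.kc * qq * std::exp(-r / M.lambda) / r;
}

struct RestraintState {
  std::vector<int> partner; // per site, -1 free
  double k = 20.0, l0 = 13.0, capture = 20.0;
  int minSep = 30;
  explicit RestraintState(int N) : partner(N, -1) {}
  double energyPair(const double* X, int i, int j) const {
    double d = dist3(X + 3*i, X + 3*j) - l0;
    return k * d * d;
  }
};

static void fullEnergy(const Model& M, const double* X, const double* twist,
                       const int* folded, const RestraintState* rs, double* E) {
  for (int c = 0; c < NCOMP; ++c) E[c] = 0.0;
  int nB = (int)M.bI.size(), nA = (int)M.aI.size();
  for (int b = 0; b < nB; ++b) {
    double e = bondEnergyB(M, b, X, folded);
    E[M.bCls[b] == 0 ? 0 : (M.bCls[b] == 1 ? 3 : 5)] += e;
  }
  for (int a = 0; a < nA; ++a) {
    double e = angleEnergyA(M, a, X);
    E[M.aCls[a] == 0 ? 1 : (M.aCls[a] == 1 ? 4 : 6)] += e;
  }
  for (int r = 0; r < M.nRuns; ++r) {
    double d = twist[r] - M.twistEq[r];
    E[2] += M.twistS * d * d;
  }
  int n = (int)M.inter.size();
  for (int a = 0; a < n; ++a) {
    int i = M.inter[a];
    for (int b = a + 1; b < n; ++b) {
      int j = M.inter[b];
      pairEnergy(M, i, j, X, E[7], E[8]);
    }
  }
  if (rs) {
    for (int i = 0; i < M.N; ++i) {
      int j = rs->partner[i];
      if (j > i) E[9] += rs->energyPair(X, i, j);
    }
  }
}

// [[Rcpp::export(name = ".cppTotalEnergy")]]
NumericVector cppTotalEnergy(List model, NumericVector coords, NumericVector twist,
                             LogicalVector tailFolded, IntegerMatrix restraints,
                             double restraintK, double restraintL0) {
  Model M = loadModel(model);
  std::vector<int> folded(M.nC, 0);
  for (int c = 0; c < M.nC; ++c) folded[c] = tailFolded[c] ? 1 : 0;
  RestraintState rs(M.N);
  rs.k = restraintK; rs.l0 = restraintL0;
  for (int r = 0; r < restraints.nrow(); ++r) {
    int i = restraints(r, 0) - 1, j = restraints(r, 1) - 1;
    rs.partner[i] = j; rs.partner[j] = i;
  }
  std::vector<double> E(NCOMP);
  std::vector<double> tw(twist.begin(), twist.end());
  fullEnergy(M, REAL(coords), tw.data(), folded.data(), &rs, E.data());
  NumericVector out(NCOMP + 1);
  double tot = 0;
  for (int c = 0; c < NCOMP; ++c) { out[c] = E[c]; tot += E[c]; }
  out[NCOMP] = tot;
  out.attr("names") = CharacterVector::create("ES","EB","ET","EtS","EtB",
            "ElhS","ElhB","EV","EC","ETF","total");
  return out;
}

// ---------------------------------------------------------------------------
// Restraint updates (greedy nearest-pair-first, one restraint per bead)
// ---------------------------------------------------------------------------
struct Event { double step; int i, j, engage; };

static bool sepOK(const Model& M, int i, int j, int minSep) {
  return std::abs(M.linkerIndex[i] - M.linkerIndex[j]) >= minSep;
}

static void refreshRestraints(const Model& M, const double* X, RestraintState& rs,
                              double step, std::vector<Event>* log, double* Etf) {
  // release engaged pairs separated beyond the capture radius
  for (int idx = 0; idx < (int)M.bindableSites.size(); ++idx) {
    int i = M.bindableSites[idx];
    int j = rs.partner[i];
    if (j > i) {
      double d = dist3(X + 3*i, X + 3*j);
      if (d > rs.capture) {
        if (Etf) *Etf -= rs.energyPair(X, i, j);
        rs.partner[i] = -1; rs.partner[j] = -1;
        if (log) log->push_back({step, i, j, 0});
      }
    }
  }
  // engage free eligible pairs, nearest first
  struct Cand { double d; int i, j; };
  std::vector<Cand> cand;
  int nb = (int)M.bindableSites.size();
  for (int a = 0; a < nb; ++a) {
    int i = M.bindableSites[a];
    if (rs.partner[i] >= 0) continue;
    for (int b = a + 1; b < nb; ++b) {
      int j = M.bindableSites[b];
      if (rs.partner[j] >= 0) continue;
      if (!sepOK(M, i, j, rs.minSep)) continue;
      double d = dist3(X + 3*i, X + 3*j);
      if (d < rs.capture) cand.push_back({d, std::min(i,j), std::max(i,j)});
    }
  }
  std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  for (const Cand& c : cand) {
    if (rs.partner[c.i] >= 0 || rs.partner[c.j] >= 0) continue;
    rs.partner[c.i] = c.j; rs.partner[c.j] = c.i;
    if (Etf) *Etf += rs.energyPair(X, c.i, c.j);
    if (log) log->push_back({step, c.i, c.j, 1});
  }
}

// update restraints touching one displaced bindable bead
static void updateBeadRestraint(const Model& M, const double* X, RestraintState& rs,
                                int s, double step, std::vector<Event>* log, double* Etf) {
  int j = rs.partner[s];
  if (j >= 0) {
    double d = dist3(X + 3*s, X + 3*j);
    if (d > rs.capture) {
      if (Etf) *Etf -= rs.energyPair(X, s, j);
      rs.partner[s] = -1; rs.partner[j] = -1;
      if (log) log->push_back({step, std::min(s,j), std::max(s,j), 0});
    }
  }
  if (rs.partner[s] < 0) {
    int best = -1; double bestD = rs.capture;
    for (int i : M.bindableSites) {
      if (i == s || rs.partner[i] >= 0) continue;
      if (!sepOK(M, s, i, rs.minSep)) continue;
      double d = dist3(X + 3*s, X + 3*i);
      if (d < bestD || (d == bestD && best >= 0 && i < best)) { bestD = d; best = i; }
    }
    if (best >= 0) {
      rs.partner[s] = best; rs.partner[best] = s;
      if (Etf) *Etf += rs.energyPair(X, s, best);
      if (log) log->push_back({step, std::min(s,best), std::max(s,best), 1});
    }
  }
}

// [[Rcpp::export(name = ".cppUpdateRestraints")]]
IntegerMatrix cppUpdateRestraints(List model, NumericVector coords,
                                  IntegerMatrix current, double k, double l0,
                                  double capture, int minSep) {
  Model M = loadModel(model);
  RestraintState rs(M.N);
  rs.k = k; rs.l0 = l0; rs.capture = capture; rs.minSep = minSep;
  for (int r = 0; r < current.nrow(); ++r) {
    int i = current(r, 0) - 1, j = current(r, 1) - 1;
    rs.partner[i] = j; rs.partner[j] = i;
  }
  refreshRestraints(M, REAL(coords), rs, 0.0, nullptr, nullptr);
  std::vector<std::pair<int,int>> pairs;
  for (int i = 0; i < M.N; ++i)
    if (rs.partner[i] > i) pairs.push_back({i + 1, rs.partner[i] + 1});
  IntegerMatrix out((int)pairs.size(), 2);
  for (int r = 0; r < (int)pairs.size(); ++r) {
    out(r, 0) = pairs[r].first; out(r, 1) = pairs[r].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// MC machinery
// ---------------------------------------------------------------------------
struct McState {
  std::vector<double> X;       // 3N
  std::vector<double> F;       // 9 * nC row-major frames
  std::vector<double> twist;   // per run (radians)
  std::vector<int> folded;     // per core
  double E[NCOMP];
  double Etf() const { return E[9]; }
};

// bonded energy delta: recompute the given bond/angle id sets
static double bondedSubset(const Model& M, const double* X, const int* folded,
                           const std::vector<int>& bondIds,
                           const std::vector<int>& angleIds, double* comp) {
  double tot = 0;
  for (int b : bondIds) {
    double e = bondEnergyB(M, b, X, folded);
    comp[M.bCls[b] == 0 ? 0 : (M.bCls[b] == 1 ? 3 : 5)] += e;
    tot += e;
  }
  for (int a : angleIds) {
    double e = angleEnergyA(M, a, X);
    comp[M.aCls[a] == 0 ? 1 : (M.aCls[a] == 1 ? 4 : 6)] += e;
    tot += e;
  }
  return tot;
}

// nonbonded energy of one site vs all other interacting sites (exclusions applied)
static void siteNonbonded(const Model& M, const double* X, int s,
                          double& ev, double& ec) {
  for (int j : M.inter) {
    if (j == s) continue;
    pairEnergy(M, s, j, X, ev, ec);
  }
}

// nonbonded cross energy: moved set vs everything else (movedFlag marks set)
static void crossNonbonded(const Model& M, const double* X,
                           const std::vector<int>& moved,
                           const std::vector<char>& movedFlag,
                           double& ev, double& ec) {
  for (int i : moved) {
    if (!M.interacting[i]) continue;
    for (int j : M.inter) {
      if (movedFlag[j]) continue;
      pairEnergy(M, i, j, X, ev, ec);
    }
  }
}

// group-blocked cross energy for large moved sets (pivot)
static void crossNonbondedBlocked(const Model& M, const double* X,
                                  const std::vector<char>& movedFlag,
                                  double& ev, double& ec) {
  int nG = M.nC;
  std::vector<double> cen(2 * nG * 3, 0.0);
  std::vector<double> rad(2 * nG, 0.0);
  std::vector<int> cnt(2 * nG, 0);
  std::vector<std::vector<int>> mem(2 * nG);
  for (int i : M.inter) {
    int g = M.group[i] + (movedFlag[i] ? nG : 0);
    mem[g].push_back(i);
    cen[3*g] += X[3*i]; cen[3*g+1] += X[3*i+1]; cen[3*g+2] += X[3*i+2];
    cnt[g]++;
  }
  for (int g = 0; g < 2 * nG; ++g)
    if (cnt[g]) { cen[3*g] /= cnt[g]; cen[3*g+1] /= cnt[g]; cen[3*g+2] /= cnt[g]; }
  for (int g = 0; g < 2 * nG; ++g)
    for (int i : mem[g]) {
      double d = dist3(&cen[3*g], X + 3*i);
      if (d > rad[g]) rad[g] = d;
    }
  for (int gm = nG; gm < 2 * nG; ++gm) {
    if (!cnt[gm]) continue;
    for (int gu = 0; gu < nG; ++gu) {
      if (!cnt[gu]) continue;
      double d = dist3(&cen[3*gm], &cen[3*gu]);
      if (d > rad[gm] + rad[gu] + M.rcut) continue;
      for (int i : mem[gm])
        for (int j : mem[gu])
          pairEnergy(M, i, j, X, ev, ec);
    }
  }
}

// restraint energy subset for pairs touching moved sites (one end moved)
static double restraintCross(const Model& M, const double* X, const RestraintState& rs,
                             const std::vector<char>& movedFlag) {
  double e = 0;
  for (int i : M.bindableSites) {
    int j = rs.partner[i];
    if (j > i && (movedFlag[i] != movedFlag[j])) e += rs.energyPair(X, i, j);
  }
  return e;
}
static double restraintSite(const Model& M, const double* X, const RestraintState& rs, int s) {
  int j = rs.partner[s];
  if (j < 0) return 0.0;
  return rs.energyPair(X, s, j);
}

// [[Rcpp::export(name = ".cppRunReplica")]]
List cppRunReplica(List model, NumericVector coords0, NumericMatrix frames0,
                   NumericVector twist0, LogicalVector tailFolded,
                   IntegerMatrix restr0, NumericVector rpar, List mc) {
  Model M = loadModel(model);
  McState S;
  S.X.assign(coords0.begin(), coords0.end());
  S.F.resize(9 * M.nC);
  for (int c = 0; c < M.nC; ++c)
    for (int k = 0; k < 9; ++k) S.F[9*c + k] = frames0(c, k);
  S.twist.assign(twist0.begin(), twist0.end());
  S.folded.resize(M.nC);
  for (int c = 0; c < M.nC; ++c) S.folded[c] = tailFolded[c] ? 1 : 0;

  RestraintState rs(M.N);
  rs.k = rpar[0]; rs.l0 = rpar[1]; rs.capture = rpar[2]; rs.minSep = (int)rpar[3];
  for (int r = 0; r < restr0.nrow(); ++r) {
    int i = restr0(r, 0) - 1, j = restr0(r, 1) - 1;
    rs.partner[i] = j; rs.partner[j] = i;
  }

  double nStepsD = as<double>(mc["nSteps"]);
  double saveEveryD = as<double>(mc["saveEvery"]);
  int64_t nSteps = (int64_t)nStepsD, saveEvery = (int64_t)saveEveryD;
  uint64_t seed = (uint64_t)as<double>(mc["seed"]);
  NumericVector weights = mc["weights"];       // pivot, linker, core, lh, tail
  double ampLinker = as<double>(mc["ampLinker"]);
  double ampCore = as<double>(mc["ampCore"]);
  double rotCore = as<double>(mc["rotCore"]);      // radians
  double ampLh = as<double>(mc["ampLh"]);
  double ampPivot = as<double>(mc["ampPivot"]);    // radians
  int nTrials = as<int>(mc["nTrials"]);
  int64_t refreshEvery = (int64_t)as<double>(mc["refreshEvery"]);

  Rng rng(seed);
  double cw[5]; double wsum = 0;
  for (int k = 0; k < 5; ++k) { wsum += weights[k]; cw[k] = wsum; }
  for (int k = 0; k < 5; ++k) cw[k] /= wsum;

  fullEnergy(M, S.X.data(), S.twist.data(), S.folded.data(), &rs, S.E);

  std::vector<Event> events;
  int64_t tried[5] = {0,0,0,0,0}, acc[5] = {0,0,0,0,0};
  int nFrames = (int)(nSteps / saveEvery);
  List frCoords(nFrames), frFrames(nFrames), frRestraints(nFrames);
  NumericMatrix frEnergy(nFrames, NCOMP + 1);
  int frameIdx = 0;
  double maxDrift = 0.0;

  std::vector<char> movedFlag(M.N, 0);
  std::vector<int> movedList;
  std::vector<double> Xtmp(3 * M.N);
  const double beta = 1.0 / M.kBT;

  auto saveFrame = [&](int idx) {
    double Echk[NCOMP];
    fullEnergy(M, S.X.data(), S.twist.data(), S.folded.data(), &rs, Echk);
    double tot0 = 0, tot1 = 0;
    for (int c = 0; c < NCOMP; ++c) { tot0 += S.E[c]; tot1 += Echk[c]; }
    maxDrift = std::max(maxDrift, std::abs(tot0 - tot1));
    for (int c = 0; c < NCOMP; ++c) S.E[c] = Echk[c];
    if (!std::isfinite(tot1)) stop("energy overflow (non-finite total energy)");
    NumericMatrix xc(M.N, 3);
    for (int i = 0; i < M.N; ++i)
      for (int d = 0; d < 3; ++d) xc(i, d) = S.X[3*i + d];
    NumericMatrix ff(M.nC, 9);
    for (int c = 0; c < M.nC; ++c)
      for (int k = 0; k < 9; ++k) ff(c, k) = S.F[9*c + k];
    std::vector<std::pair<int,int>> pairs;
    for (int i = 0; i < M.N; ++i)
      if (rs.partner[i] > i) pairs.push_back({i + 1, rs.partner[i] + 1});
    IntegerMatrix rm((int)pairs.size(), 2);
    for (int r = 0; r < (int)pairs.size(); ++r) {
      rm(r, 0) = pairs[r].first; rm(r, 1) = pairs[r].second;
    }
    frCoords[idx] = xc; frFrames[idx] = ff; frRestraints[idx] = rm;
    double tot = 0;
    for (int c = 0; c < NCOMP; ++c) { frEnergy(idx, c) = S.E[c]; tot += S.E[c]; }
    frEnergy(idx, NCOMP) = tot;
  };

  // gather unique bonded term ids for a moved set
  std::vector<int> bondIds, angleIds;
  auto gatherBonded = [&](const std::vector<int>& moved) {
    bondIds.clear(); angleIds.clear();
    for (int s : moved) {
      for (int b : M.siteBonds[s]) bondIds.push_back(b);
      for (int a : M.siteAngles[s]) angleIds.push_back(a);
    }
    std::sort(bondIds.begin(), bondIds.end());
    bondIds.erase(std::unique(bondIds.begin(), bondIds.end()), bondIds.end());
    std::sort(angleIds.begin(), angleIds.end());
    angleIds.erase(std::unique(angleIds.begin(), angleIds.end()), angleIds.end());
  };

  for (int64_t step = 1; step <= nSteps; ++step) {
    double u = rng.unif();
    int kind = 0;
    while (kind < 4 && u > cw[kind]) ++kind;
    tried[kind]++;

    if (kind == 0 && !M.linkerSites.empty() && M.nC >= 2) {
      // ---- global pivot ----
      int p = M.linkerSites[rng.sampleInt((int)M.linkerSites.size())];
      int pPos = M.chainPos[p];
      int coresBefore = 0;
      for (int c = 0; c < M.nC; ++c)
        if (M.chainPos[M.coreSite[c]] < pPos) coresBefore++;
      bool moveBefore = coresBefore <= (M.nC - coresBefore);
      movedList.clear();
      for (int i = 0; i < M.N; ++i) {
        int pos = M.chainPos[i];
        bool mv = moveBefore ? (pos < pPos) : (pos > pPos);
        movedFlag[i] = mv ? 1 : 0;
        if (mv) movedList.push_back(i);
      }
      if (!movedList.empty()) {
        double axis[3]; rng.unitVec(axis);
        double th = ampPivot * rng.unifSym();
        double R[9]; rotMat(axis, th, R);
        const double* piv = S.X.data() + 3 * p;
        // old energies
        double evO = 0, ecO = 0;
        crossNonbondedBlocked(M, S.X.data(), movedFlag, evO, ecO);
        gatherBonded(movedList);
        double compO[NCOMP] = {0}, compN[NCOMP] = {0};
        bondedSubset(M, S.X.data(), S.folded.data(), bondIds, angleIds, compO);
        double rtO = restraintCross(M, S.X.data(), rs, movedFlag);
        // propose
        std::copy(S.X.begin(), S.X.end(), Xtmp.begin());
        for (int i : movedList) {
          double v[3] = { S.X[3*i] - piv[0], S.X[3*i+1] - piv[1], S.X[3*i+2] - piv[2] };
          double w[3]; applyRot(R, v, w);
          Xtmp[3*i] = piv[0] + w[0]; Xtmp[3*i+1] = piv[1] + w[1]; Xtmp[3*i+2] = piv[2] + w[2];
        }
        double evN = 0, ecN = 0;
        crossNonbondedBlocked(M, Xtmp.data(), movedFlag, evN, ecN);
        bondedSubset(M, Xtmp.data(), S.folded.data(), bondIds, angleIds, compN);
        double rtN = restraintCross(M, Xtmp.data(), rs, movedFlag);
        double dE = (evN - evO) + (ecN - ecO) + (rtN - rtO);
        for (int c = 0; c < 7; ++c) dE += compN[c] - compO[c];
        if (dE <= 0 || rng.unif() < std::exp(-beta * dE)) {
          acc[0]++;
          for (int i : movedList)
            for (int d = 0; d < 3; ++d) S.X[3*i + d] = Xtmp[3*i + d];
          for (int c = 0; c < M.nC; ++c) {
            if (!movedFlag[M.coreSite[c]]) continue;
            double Fn[9];
            // F <- R * F
            for (int r = 0; r < 3; ++r)
              for (int cc = 0; cc < 3; ++cc)
                Fn[3*r + cc] = R[3*r+0]*S.F[9*c + 0 + cc] + R[3*r+1]*S.F[9*c + 3 + cc]
                             + R[3*r+2]*S.F[9*c + 6 + cc];
            for (int k = 0; k < 9; ++k) S.F[9*c + k] = Fn[k];
          }
          for (int c = 0; c < 7; ++c) S.E[c] += compN[c] - compO[c];
          S.E[7] += evN - evO; S.E[8] += ecN - ecO; S.E[9] += rtN - rtO;
          // restraint bookkeeping for displaced bindable beads
          double preTf = S.E[9];
          refreshRestraints(M, S.X.data(), rs, (double)step, &events, &S.E[9]);
          (void)preTf;
        }
      }
    } else if (kind == 1 || kind == 3) {
      // ---- local bead translation (linker or LH) ----
      const std::vector<int>& pool = (kind == 1) ? M.linkerSites : M.lhSites;
      if (!pool.empty()) {
        int s = pool[rng.sampleInt((int)pool.size())];
        double amp = (kind == 1) ? ampLinker : ampLh;
        double d[3]; rng.unitBall(d);
        double oldP[3] = { S.X[3*s], S.X[3*s+1], S.X[3*s+2] };
        double newP[3] = { oldP[0] + amp*d[0], oldP[1] + amp*d[1], oldP[2] + amp*d[2] };
        double compO[NCOMP] = {0}, compN[NCOMP] = {0};
        bondedSubset(M, S.X.data(), S.folded.data(), M.siteBonds[s], M.siteAngles[s], compO);
        double evO = 0, ecO = 0; siteNonbonded(M, S.X.data(), s, evO, ecO);
        double rtO = restraintSite(M, S.X.data(), rs, s);
        for (int dd = 0; dd < 3; ++dd) S.X[3*s + dd] = newP[dd];
        bondedSubset(M, S.X.data(), S.folded.data(), M.siteBonds[s], M.siteAngles[s], compN);
        double evN = 0, ecN = 0; siteNonbonded(M, S.X.data(), s, evN, ecN);
        double rtN = restraintSite(M, S.X.data(), rs, s);
        double dE = (evN - evO) + (ecN - ecO) + (rtN - rtO);
        for (int c = 0; c < 7; ++c) dE += compN[c] - compO[c];
        if (dE <= 0 || rng.unif() < std::exp(-beta * dE)) {
          acc[kind]++;
          for (int c = 0; c < 7; ++c) S.E[c] += compN[c] - compO[c];
          S.E[7] += evN - evO; S.E[8] += ecN - ecO; S.E[9] += rtN - rtO;
          if (M.bindable[s])
            updateBeadRestraint(M, S.X.data(), rs, s, (double)step, &events, &S.E[9]);
        } else {
          for (int dd = 0; dd < 3; ++dd) S.X[3*s + dd] = oldP[dd];
        }
      }
    } else if (kind == 2) {
      // ---- local core move: translate or rotate the rigid unit ----
      int c = rng.sampleInt(M.nC);
      bool rotate = rng.unif() < 0.5;
      movedList.clear();
      movedList.push_back(M.coreSite[c]);
      for (int i : M.children[c]) if (i != M.coreSite[c]) movedList.push_back(i);
      for (int i : movedList) movedFlag[i] = 1;
      gatherBonded(movedList);
      double compO[NCOMP] = {0}, compN[NCOMP] = {0};
      bondedSubset(M, S.X.data(), S.folded.data(), bondIds, angleIds, compO);
      double evO = 0, ecO = 0;
      crossNonbonded(M, S.X.data(), movedList, movedFlag, evO, ecO);
      std::vector<double> oldPos(3 * movedList.size());
      for (size_t k = 0; k < movedList.size(); ++k)
        for (int d = 0; d < 3; ++d) oldPos[3*k + d] = S.X[3*movedList[k] + d];
      double R[9] = {1,0,0,0,1,0,0,0,1};
      if (rotate) {
        double axis[3]; rng.unitVec(axis);
        double th = rotCore * rng.unifSym();
        rotMat(axis, th, R);
        const double* ctr = S.X.data() + 3 * M.coreSite[c];
        double c0[3] = { ctr[0], ctr[1], ctr[2] };
        for (int i : movedList) {
          double v[3] = { S.X[3*i] - c0[0], S.X[3*i+1] - c0[1], S.X[3*i+2] - c0[2] };
          double w[3]; applyRot(R, v, w);
          S.X[3*i] = c0[0] + w[0]; S.X[3*i+1] = c0[1] + w[1]; S.X[3*i+2] = c0[2] + w[2];
        }
      } else {
        double d[3]; rng.unitBall(d);
        for (int i : movedList) {
          S.X[3*i] += ampCore * d[0]; S.X[3*i+1] += ampCore * d[1]; S.X[3*i+2] += ampCore * d[2];
        }
      }
      bondedSubset(M, S.X.data(), S.folded.data(), bondIds, angleIds, compN);
      double evN = 0, ecN = 0;
      crossNonbonded(M, S.X.data(), movedList, movedFlag, evN, ecN);
      double dE = (evN - evO) + (ecN - ecO);
      for (int cc = 0; cc < 7; ++cc) dE += compN[cc] - compO[cc];
      if (dE <= 0 || rng.unif() < std::exp(-beta * dE)) {
        acc[2]++;
        for (int cc = 0; cc < 7; ++cc) S.E[cc] += compN[cc] - compO[cc];
        S.E[7] += evN - evO; S.E[8] += ecN - ecO;
        if (rotate) {
          double Fn[9];
          for (int r = 0; r < 3; ++r)
            for (int cc = 0; cc < 3; ++cc)
              Fn[3*r + cc] = R[3*r+0]*S.F[9*c + 0 + cc] + R[3*r+1]*S.F[9*c + 3 + cc]
                           + R[3*r+2]*S.F[9*c + 6 + cc];
          for (int k = 0; k < 9; ++k) S.F[9*c + k] = Fn[k];
        }
      } else {
        for (size_t k = 0; k < movedList.size(); ++k)
          for (int d = 0; d < 3; ++d) S.X[3*movedList[k] + d] = oldPos[3*k + d];
      }
      for (int i : movedList) movedFlag[i] = 0;
    } else if (kind == 4 && !M.tails.empty()) {
      // ---- Rosenbluth tail regrowth ----
      int t = rng.sampleInt((int)M.tails.size());
      const std::vector<int>& beads = M.tails[t];
      int attach = M.tailAttach[t];
      int tc = M.tailCore[t];
      int m = (int)beads.size();
      // candidate nonbonded sites: groups within reach of the attachment
      double reach = 0;
      {
        const double* prev = S.X.data() + 3 * attach;
        for (int b : beads) { reach += dist3(prev, S.X.data() + 3*b); prev = S.X.data() + 3*b; }
      }
      reach += M.rcut + 1.0;
      std::vector<int> cand;
      {
        std::vector<double> cen(3 * M.nC, 0.0);
        std::vector<double> rad(M.nC, 0.0);
        std::vector<int> cnt(M.nC, 0);
        for (int i : M.inter) {
          int g = M.group[i];
          cen[3*g] += S.X[3*i]; cen[3*g+1] += S.X[3*i+1]; cen[3*g+2] += S.X[3*i+2];
          cnt[g]++;
        }
        for (int g = 0; g < M.nC; ++g)
          if (cnt[g]) { cen[3*g] /= cnt[g]; cen[3*g+1] /= cnt[g]; cen[3*g+2] /= cnt[g]; }
        for (int i : M.inter) {
          int g = M.group[i];
          double d = dist3(&cen[3*g], S.X.data() + 3*i);
          if (d > rad[g]) rad[g] = d;
        }
        const double* A = S.X.data() + 3 * attach;
        for (int g = 0; g < M.nC; ++g) {
          if (!cnt[g]) continue;
          if (dist3(&cen[3*g], A) > rad[g] + reach) continue;
          for (int i : M.inter)
            if (M.group[i] == g && M.parent[i] != tc) cand.push_back(i);
        }
      }
      // tail bead angle constant (acetylation-scaled) — all tail angles of a
      // chain share one g; read it from the model's angle table
      double gTail = 0.0;
      if (m >= 2) {
        for (int a : M.siteAngles[beads[1]])
          if (M.aCls[a] == 1 && M.aJ[a] == beads[0]) { gTail = M.aG[a]; break; }
        if (gTail == 0.0)
          for (int a : M.siteAngles[beads[0]])
            if (M.aCls[a] == 1) { gTail = M.aG[a]; break; }
      }
      auto beadU = [&](int beadSite, const double* p, const double* prev,
                       const double* prev2) -> double {
        double u = 0;
        if (prev2) {
          double th = bendTheta(prev2, prev, p);
          u += gTail * th * th;
        }
        double ev = 0, ec = 0;
        for (int j : cand) {
          double r2 = dist2of(p, S.X.data() + 3*j);
          if (r2 > M.rcut * M.rcut) continue;
          double r = std::sqrt(r2);
          if (M.radius[beadSite] > 0 && M.radius[j] > 0) {
            double sig = M.radius[beadSite] + M.radius[j];
            if (r < sig) {
              double s6 = sig*sig / std::max(r2, 1e-12); s6 = s6*s6*s6;
              ev += M.kev * (s6*s6 - 2.0*s6 + 1.0);
            }
          }
          double qq = M.charge[beadSite] * M.charge[j];
          if (qq != 0.0 && r > 1e-9) ec += M.kc * qq * std::exp(-r / M.lambda) / r;
        }
        return u + ev + ec;
      };

      std::vector<double> newPos(3 * m), blen(m);
      {
        const double* prev = S.X.data() + 3 * attach;
        for (int k = 0; k < m; ++k) {
          blen[k] = dist3(prev, S.X.data() + 3*beads[k]);
          prev = S.X.data() + 3*beads[k];
        }
      }
      double logWn = 0, logWo = 0;
      bool dead = false;
      // grow new configuration
      {
        double prev[3] = { S.X[3*attach], S.X[3*attach+1], S.X[3*attach+2] };
        double prev2[3]; bool hasPrev2 = false;
        for (int k = 0; k < m && !dead; ++k) {
          double wsumT = 0;
          std::vector<double> us(nTrials);
          std::vector<double> ps(3 * nTrials);
          for (int tr = 0; tr < nTrials; ++tr) {
            double dir[3]; rng.unitVec(dir);
            double p[3] = { prev[0] + blen[k]*dir[0], prev[1] + blen[k]*dir[1],
                            prev[2] + blen[k]*dir[2] };
            us[tr] = beadU(beads[k], p, prev, hasPrev2 ? prev2 : nullptr);
            ps[3*tr] = p[0]; ps[3*tr+1] = p[1]; ps[3*tr+2] = p[2];
            wsumT += std::exp(-beta * us[tr]);
          }
          if (wsumT <= 0 || !std::isfinite(wsumT)) { dead = true; break; }
          logWn += std::log(wsumT);
          double pick = rng.unif() * wsumT, accw = 0;
          int chosen = nTrials - 1;
          for (int tr = 0; tr < nTrials; ++tr) {
            accw += std::exp(-beta * us[tr]);
            if (pick <= accw) { chosen = tr; break; }
          }
          prev2[0] = prev[0]; prev2[1] = prev[1]; prev2[2] = prev[2]; hasPrev2 = true;
          prev[0] = ps[3*chosen]; prev[1] = ps[3*chosen+1]; prev[2] = ps[3*chosen+2];
          newPos[3*k] = prev[0]; newPos[3*k+1] = prev[1]; newPos[3*k+2] = prev[2];
        }
      }
      if (!dead) {
        // retrace old configuration
        double prev[3] = { S.X[3*attach], S.X[3*attach+1], S.X[3*attach+2] };
        double prev2[3]; bool hasPrev2 = false;
        for (int k = 0; k < m; ++k) {
          const double* oldP = S.X.data() + 3*beads[k];
          double wsumT = std::exp(-beta * beadU(beads[k], oldP, prev,
                                               hasPrev2 ? prev2 : nullptr));
          for (int tr = 1; tr < nTrials; ++tr) {
            double dir[3]; rng.unitVec(dir);
            double p[3] = { prev[0] + blen[k]*dir[0], prev[1] + blen[k]*dir[1],
                            prev[2] + blen[k]*dir[2] };
            wsumT += std::exp(-beta * beadU(beads[k], p, prev, hasPrev2 ? prev2 : nullptr));
          }
          logWo += std::log(wsumT);
          prev2[0] = prev[0]; prev2[1] = prev[1]; prev2[2] = prev[2]; hasPrev2 = true;
          prev[0] = oldP[0]; prev[1] = oldP[1]; prev[2] = oldP[2];
        }
        if (std::log(rng.unif() + 1e-300) < logWn - logWo) {
          acc[4]++;
          // component deltas (angles EtB; nonbonded EV/EC) over candidate set
          double dEtB = 0, dEV = 0, dEC = 0;
          gatherBonded(beads);
          // angles old
          for (int a : angleIds) {
            double e = angleEnergyA(M, a, S.X.data());
            if (M.aCls[a] == 1) dEtB -= e;
          }
          double evO = 0, ecO = 0;
          for (int b : beads) {
            for (int j : cand) {
              if (M.excluded(b, j)) continue;
              pairEnergy(M, b, j, S.X.data(), evO, ecO);
            }
          }
          for (int k = 0; k < m; ++k)
            for (int d = 0; d < 3; ++d) S.X[3*beads[k] + d] = newPos[3*k + d];
          for (int a : angleIds) {
            double e = angleEnergyA(M, a, S.X.data());
            if (M.aCls[a] == 1) dEtB += e;
          }
          double evN = 0, ecN = 0;
          for (int b : beads) {
            for (int j : cand) {
              if (M.excluded(b, j)) continue;
              pairEnergy(M, b, j, S.X.data(), evN, ecN);
            }
          }
          dEV = evN - evO; dEC = ecN - ecO;
          S.E[4] += dEtB; S.E[7] += dEV; S.E[8] += dEC;
        }
      }
    }

    if (refreshEvery > 0 && step % refreshEvery == 0)
      refreshRestraints(M, S.X.data(), rs, (double)step, &events, &S.E[9]);
    if (step % saveEvery == 0 && frameIdx < nFrames)
      saveFrame(frameIdx++);
  }

  NumericMatrix accMat(5, 2);
  for (int k = 0; k < 5; ++k) { accMat(k, 0) = (double)tried[k]; accMat(k, 1) = (double)acc[k]; }
  int nev = (int)events.size();
  NumericVector evStep(nev); IntegerVector evI(nev), evJ(nev), evType(nev);
  for (int e = 0; e < nev; ++e) {
    evStep[e] = events[e].step; evI[e] = events[e].i + 1;
    evJ[e] = events[e].j + 1; evType[e] = events[e].engage;
  }
  return List::create(
    _["frameCoords"] = frCoords, _["frameFrames"] = frFrames,
    _["frameRestraints"] = frRestraints, _["frameEnergy"] = frEnergy,
    _["acceptance"] = accMat, _["maxDrift"] = maxDrift,
    _["events"] = DataFrame::create(_["step"] = evStep, _["i"] = evI,
                                    _["j"] = evJ, _["engaged"] = evType));
}

// ---------------------------------------------------------------------------
// Single Rosenbluth regrowth (R-level op): returns proposal + log weight ratio
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppRegrowTail")]]
List cppRegrowTail(List model, NumericVector coords, LogicalVector tailFolded,
                   int tailId, int nTrials, double seed) {
  Model M = loadModel(model);
  if (tailId < 1 || tailId > (int)M.tails.size()) stop("invalid tail id");
  std::vector<double> X(coords.begin(), coords.end());
  const std::vector<int>& beads = M.tails[tailId - 1];
  int attach = M.tailAttach[tailId - 1];
  int tc = M.tailCore[tailId - 1];
  int m = (int)beads.size();
  Rng rng((uint64_t)seed);
  const double beta = 1.0 / M.kBT;
  double gTail = 0.0;
  if (m >= 2) {
    for (int a : M.siteAngles[beads[1]])
      if (M.aCls[a] == 1 && M.aJ[a] == beads[0]) { gTail = M.aG[a]; break; }
  }
  std::vector<int> cand;
  for (int i : M.inter) if (M.parent[i] != tc) cand.push_back(i);
  auto beadU = [&](int beadSite, const double* p, const double* prev,
                   const double* prev2) -> double {
    double u = 0;
    if (prev2) { double th = bendTheta(prev2, prev, p); u += gTail * th * th; }
    for (int j : cand) {
      double r2 = dist2of(p, X.data() + 3*j);
      if (r2 > M.rcut * M.rcut) continue;
      double r = std::sqrt(r2);
      if (M.radius[beadSite] > 0 && M.radius[j] > 0) {
        double sig = M.radius[beadSite] + M.radius[j];
        if (r < sig) {
          double s6 = sig*sig / std::max(r2, 1e-12); s6 = s6*s6*s6;
          u += M.kev * (s6*s6 - 2.0*s6 + 1.0);
        }
      }
      double qq = M.charge[beadSite] * M.charge[j];
      if (qq != 0.0 && r > 1e-9) u += M.kc * qq * std::exp(-r / M.lambda) / r;
    }
    return u;
  };
  std::vector<double> blen(m);
  {
    const double* prev = X.data() + 3 * attach;
    for (int k = 0; k < m; ++k) {
      blen[k] = dist3(prev, X.data() + 3*beads[k]);
      prev = X.data() + 3*beads[k];
    }
  }
  std::vector<double> newPos(3 * m);
  double logWn = 0, logWo = 0;
  {
    double prev[3] = { X[3*attach], X[3*attach+1], X[3*attach+2] };
    double prev2[3]; bool hasPrev2 = false;
    for (int k = 0; k < m; ++k) {
      double wsumT = 0;
      std::vector<double> us(nTrials), ps(3 * nTrials);
      for (int tr = 0; tr < nTrials; ++tr) {
        double dir[3]; rng.unitVec(dir);
        double p[3] = { prev[0]+blen[k]*dir[0], prev[1]+blen[k]*dir[1], prev[2]+blen[k]*dir[2] };
        us[tr] = beadU(beads[k], p, prev, hasPrev2 ? prev2 : nullptr);
        ps[3*tr] = p[0]; ps[3*tr+1] = p[1]; ps[3*tr+2] = p[2];
        wsumT += std::exp(-beta * us[tr]);
      }
      if (wsumT <= 0) stop("regrowth trapped: zero Rosenbluth weight");
      logWn += std::log(wsumT);
      double pick = rng.unif() * wsumT, accw = 0;
      int chosen = nTrials - 1;
      for (int tr = 0; tr < nTrials; ++tr) {
        accw += std::exp(-beta * us[tr]);
        if (pick <= accw) { chosen = tr; break; }
      }
      prev2[0] = prev[0]; prev2[1] = prev[1]; prev2[2] = prev[2]; hasPrev2 = true;
      prev[0] = ps[3*chosen]; prev[1] = ps[3*chosen+1]; prev[2] = ps[3*chosen+2];
      newPos[3*k] = prev[0]; newPos[3*k+1] = prev[1]; newPos[3*k+2] = prev[2];
    }
    double prevO[3] = { X[3*attach], X[3*attach+1], X[3*attach+2] };
    double prev2O[3]; bool hasPrev2O = false;
    for (int k = 0; k < m; ++k) {
      const double* oldP = X.data() + 3*beads[k];
      double wsumT = std::exp(-beta * beadU(beads[k], oldP, prevO,
                                            hasPrev2O ? prev2O : nullptr));
      for (int tr = 1; tr < nTrials; ++tr) {
        double dir[3]; rng.unitVec(dir);
        double p[3] = { prevO[0]+blen[k]*dir[0], prevO[1]+blen[k]*dir[1], prevO[2]+blen[k]*dir[2] };
        wsumT += std::exp(-beta * beadU(beads[k], p, prevO, hasPrev2O ? prev2O : nullptr));
      }
      logWo += std::log(wsumT);
      prev2O[0] = prevO[0]; prev2O[1] = prevO[1]; prev2O[2] = prevO[2]; hasPrev2O = true;
      prevO[0] = oldP[0]; prevO[1] = oldP[1]; prevO[2] = oldP[2];
    }
  }
  NumericMatrix out(m, 3);
  for (int k = 0; k < m; ++k)
    for (int d = 0; d < 3; ++d) out(k, d) = newPos[3*k + d];
  return List::create(_["beadSites"] = wrap(std::vector<int>(beads.begin(), beads.end())),
                      _["newPositions"] = out,
                      _["logWeightRatio"] = logWn - logWo);
}

// ---------------------------------------------------------------------------
// Contact maps: per-frame binary contact between bins, accumulated over frames
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppContactCounts")]]
NumericMatrix cppContactCounts(List frames, IntegerVector elemBin,
                               NumericVector elemRadius, int nBins, double cutoff) {
  int nE = elemBin.size();
  NumericMatrix counts(nBins, nBins);
  std::vector<char> touch((size_t)nBins * nBins);
  for (int f = 0; f < frames.size(); ++f) {
    NumericMatrix X = frames[f];
    if (X.nrow() != nE) stop("frame/element size mismatch");
    std::fill(touch.begin(), touch.end(), 0);
    for (int i = 0; i < nE; ++i) {
      int bi = elemBin[i] - 1;
      if (bi < 0) continue;
      for (int j = i + 1; j < nE; ++j) {
        int bj = elemBin[j] - 1;
        if (bj < 0 || bj == bi) continue;
        double thr = cutoff + elemRadius[i] + elemRadius[j];
        double dx = X(i,0)-X(j,0), dy = X(i,1)-X(j,1), dz = X(i,2)-X(j,2);
        if (dx*dx + dy*dy + dz*dz < thr*thr) {
          touch[(size_t)bi * nBins + bj] = 1;
          touch[(size_t)bj * nBins + bi] = 1;
        }
      }
    }
    for (int a = 0; a < nBins; ++a)
      for (int b = 0; b < nBins; ++b)
        if (touch[(size_t)a * nBins + b]) counts(a, b) += 1.0;
  }
  return counts;
}
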