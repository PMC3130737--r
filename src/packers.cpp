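// Combinatorial side-chain packing kernels.
//
// A packing problem arrives from R as a list:
//   m        integer vector, rotamers per position
//   one_body list of numeric vectors (length m[p])
//   pi, pj   1-based endpoints of neighbor pairs (pi < pj)
//   mats     list of numeric matrices, m[pi] x m[pj] pair energies
//   e_const  scalar background energy
// Assignments are 0-based internally, 1-based at the R boundary.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic, platform-independent RNG (splitmix64).  Packer results must
// be a pure function of (problem, seed), independent of R's RNG state.
struct Rng {
  uint64_t s;
  explicit Rng(double seed) : s(static_cast<uint64_t>(seed)) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Edge { int other; int pair; bool first; };

struct Problem {
  int n;
  std::vector<int> m;
  std::vector<std::vector<double> > ob;      // one-body
  std::vector<int> pi, pj;                   // 0-based
  std::vector<std::vector<double> > mat;     // row-major m[pi] x m[pj]
  std::vector<std::vector<Edge> > adj;
  std::vector<int> movable;                  // positions with m > 1
  double e_const;

  explicit Problem(const List& prob) {
    IntegerVector mm = prob["m"];
    n = mm.size();
    m.assign(mm.begin(), mm.end());
    List obl = prob["one_body"];
    ob.resize(n);
    for (int p = 0; p < n; ++p) {
      NumericVector v = obl[p];
      ob[p].assign(v.begin(), v.end());
    }
    IntegerVector pii = prob["pi"], pjj = prob["pj"];
    List mats = prob["mats"];
    int np = pii.size();
    pi.resize(np); pj.resize(np); mat.resize(np);
    adj.resize(n);
    for (int k = 0; k < np; ++k) {
      pi[k] = pii[k] - 1; pj[k] = pjj[k] - 1;
      NumericMatrix M = mats[k];
      mat[k].resize(M.nrow() * M.ncol());
      for (int r = 0; r < M.nrow(); ++r)
        for (int c = 0; c < M.ncol(); ++c)
          mat[k][r * M.ncol() + c] = M(r, c);
      adj[pi[k]].push_back(Edge{pj[k], k, true});
      adj[pj[k]].push_back(Edge{pi[k], k, false});
    }
    e_const = as<double>(prob["e_const"]);
    for (int p = 0; p < n; ++p) if (m[p] > 1) movable.push_back(p);
  }

  inline double pairval(int k, int ri, int rj) const {
    // ri indexes pi[k]'s rotamers, rj indexes pj[k]'s
    return mat[k][ri * m[pj[k]] + rj];
  }
  // one-body + interactions of rotamer r at p with the current assignment
  inline double contrib(int p, int r, const std::vector<int>& a) const {
    double e = ob[p][r];
    for (size_t t = 0; t < adj[p].size(); ++t) {
      const Edge& ed = adj[p][t];
      e += ed.first ? pairval(ed.pair, r, a[ed.other])
                    : pairval(ed.pair, a[ed.other], r);
    }
    return e;
  }
  double total(const std::vector<int>& a) const {
    double e = e_const;
    for (int p = 0; p < n; ++p) e += ob[p][a[p]];
    for (size_t k = 0; k < pi.size(); ++k) e += pairval((int)k, a[pi[k]], a[pj[k]]);
    return e;
  }
  int best_rot(int p, const std::vector<int>& a) const {
    int best = 0; double be = contrib(p, 0, a);
    for (int r = 1; r < m[p]; ++r) {
      double e = contrib(p, r, a);
      if (e < be) { be = e; best = r; }
    }
    return best;
  }
  std::vector<int> bmec() const {
    std::vector<int> a(n, 0);
    for (int p = 0; p < n; ++p) {
      int best = 0; double be = ob[p][0];
      for (int r = 1; r < m[p]; ++r)
        if (ob[p][r] < be) { be = ob[p][r]; best = r; }
      a[p] = best;
    }
    return a;
  }
};

// Fixed-order sweeps accepting strictly energy-lowering single substitutions.
static void quench_inplace(const Problem& P, std::vector<int>& a) {
  bool any = true;
  while (any) {
    any = false;
    for (int p = 0; p < P.n; ++p) {
      double cur = P.contrib(p, a[p], a);
      for (int r = 0; r < P.m[p]; ++r) {
        if (r == a[p]) continue;
        double e = P.contrib(p, r, a);
        if (e < cur) { a[p] = r; cur = e; any = true; }
      }
    }
  }
}

// FASTER-style single-residue perturbation/relaxation sweeps from `a`.
// Each perturbation fixes one rotamer and relaxes the <=10 neighbors with
// greatest-magnitude interaction with it; accepted iff the net energy
// strictly decreases.
struct Trace { std::vector<double> move; std::vector<double> best; };

static void spr_inplace(const Problem& P, std::vector<int>& a,
                        int max_sweeps, int max_relax, int max_nbr,
                        Trace* tr, double move_offset) {
  double E = P.total(a);
  long moves = (long)move_offset;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool any = false;
    for (int p = 0; p < P.n; ++p) {
      for (int r = 0; r < P.m[p]; ++r) {
        if (r == a[p]) continue;
        ++moves;
        std::vector<int> save = a;
        a[p] = r;
        // neighbors ranked by |interaction with the perturbed rotamer|
        std::vector<std::pair<double, int> > rank;
        for (size_t t = 0; t < P.adj[p].size(); ++t) {
          const Edge& ed = P.adj[p][t];
          double v = ed.first ? P.pairval(ed.pair, r, a[ed.other])
                              : P.pairval(ed.pair, a[ed.other], r);
          rank.push_back(std::make_pair(-std::fabs(v), ed.other));
        }
        std::sort(rank.begin(), rank.end());
        int nsel = std::min((int)rank.size(), max_nbr);
        for (int pass = 0; pass < max_relax; ++pass) {
          bool changed = false;
          for (int t = 0; t < nsel; ++t) {
            int q = rank[t].second;
            int b = P.best_rot(q, a);
            if (b != a[q]) { a[q] = b; changed = true; }
          }
          if (!changed) break;
        }
        double Enew = P.total(a);
        if (Enew < E) {
          E = Enew; any = true;
          if (tr) { tr->move.push_back((double)moves); tr->best.push_back(E); }
        } else {
          a = save;
        }
      }
    }
    if (!any) break;
  }
}

static std::vector<int> random_assignment(const Problem& P, Rng& rng) {
  std::vector<int> a(P.n);
  for (int p = 0; p < P.n; ++p) a[p] = (P.m[p] == 1) ? 0 : rng.below(P.m[p]);
  return a;
}

// One Metropolis substitution; returns energy delta applied (0 if rejected).
static bool metropolis_move(const Problem& P, std::vector<int>& a, double& E,
                            double kT, Rng& rng, double* delta_out) {
  int p = P.movable[rng.below((int)P.movable.size())];
  int r = rng.below(P.m[p] - 1);
  if (r >= a[p]) ++r;
  double d = P.contrib(p, r, a) - P.contrib(p, a[p], a);
  if (delta_out) *delta_out = d;
  bool acc = (d <= 0.0) || (rng.unif() < std::exp(-d / kT));
  if (acc) { a[p] = r; E += d; }
  return acc;
}

static List result_list(const Problem& P, const std::vector<int>& a, double E,
                        double moves, double qr, const Trace& tr) {
  IntegerVector av(a.begin(), a.end());
  for (int i = 0; i < av.size(); ++i) av[i] += 1;
  return List::create(_["choice"] = av, _["energy"] = E,
                      _["moves"] = moves, _["quench_restores"] = qr,
                      _["trace_move"] = NumericVector(tr.move.begin(), tr.move.end()),
                      _["trace_best"] = NumericVector(tr.best.begin(), tr.best.end()));
}

// [[Rcpp::export]]
double cpp_total_energy(List prob, IntegerVector choice) {
  Problem P(prob);
  std::vector<int> a(choice.begin(), choice.end());
  for (int i = 0; i < P.n; ++i) a[i] -= 1;
  return P.total(a);
}

// [[Rcpp::export]]
IntegerVector cpp_bmec(List prob) {
  Problem P(prob);
  std::vector<int> a = P.bmec();
  IntegerVector out(a.begin(), a.end());
  for (int i = 0; i < out.size(); ++i) out[i] += 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_quench(List prob, IntegerVector start) {
  Problem P(prob);
  std::vector<int> a(start.begin(), start.end());
  for (int i = 0; i < P.n; ++i) a[i] -= 1;
  quench_inplace(P, a);
  IntegerVector out(a.begin(), a.end());
  for (int i = 0; i < out.size(); ++i) out[i] += 1;
  return out;
}

// [[Rcpp::export]]
List cpp_spr(List prob, IntegerVector start, int max_sweeps = 30,
             int max_relax = 10, int max_nbr = 10) {
  Problem P(prob);
  std::vector<int> a(start.begin(), start.end());
  for (int i = 0; i < P.n; ++i) a[i] -= 1;
  Trace tr;
  tr.move.push_back(0.0); tr.best.push_back(P.total(a));
  spr_inplace(P, a, max_sweeps, max_relax, max_nbr, &tr, 0.0);
  return result_list(P, a, P.total(a), tr.move.back(), 0, tr);
}

// Standard annealer: geometric cooling kT_high -> kT_low across n_outer
// outer iterations, reheat on energy plateau, restore-best + quench at end.
// [[Rcpp::export]]
List cpp_anneal_standard(List prob, double seed, int moves_per_temp,
                         int n_outer = 19, double kT_high = 100.0,
                         double kT_low = 0.3) {
  Problem P(prob);
  Rng rng(seed);
  Trace tr;
  std::vector<int> a = random_assignment(P, rng);
  double E = P.total(a);
  std::vector<int> best = a; double bestE = E;
  tr.move.push_back(0.0); tr.best.push_back(bestE);
  long moves = 0;
  if (!P.movable.empty()) {
    double factor = std::pow(kT_low / kT_high, 1.0 / (n_outer - 1));
    double kT = kT_high;
    std::vector<double> finals;
    for (int it = 0; it < n_outer; ++it) {
      for (int mv = 0; mv < moves_per_temp; ++mv) {
        ++moves;
        metropolis_move(P, a, E, kT, rng, 0);
        if (E < bestE) {
          bestE = E; best = a;
          tr.move.push_back((double)moves); tr.best.push_back(bestE);
        }
      }
      E = P.total(a);  // kill incremental drift once per temperature
      finals.push_back(E);
      if (it >= 3) {
        double avg = (finals[it - 1] + finals[it - 2] + finals[it - 3]) / 3.0;
        if (E >= avg - 1.0) kT = kT_high;   // plateaued: reheat
        else kT *= factor;
      } else {
        kT *= factor;
      }
    }
  }
  a = best;
  quench_inplace(P, a);
  double Eq = P.total(a);
  if (Eq < bestE) {
    bestE = Eq; best = a;
    tr.move.push_back((double)moves); tr.best.push_back(bestE);
  }
  return result_list(P, best, bestE, (double)moves, 0, tr);
}

// Multi-cool annealer.  Phase 1: 20 geometric temperatures 10 -> 0.2 with
// three quench-and-restore operations per temperature (60 total), keeping the
// 10 lowest-energy distinct quenched assignments.  Phase 2: six coolings
// 0.25 -> 0.05 over 10 temperatures started from the best six saved, with a
// quench-and-restore closing every temperature.
// [[Rcpp::export]]
List cpp_anneal_multicool(List prob, double seed, int moves_per_temp,
                          int n_temps1 = 20, double kT1_high = 10.0,
                          double kT1_low = 0.2, int n_traj2 = 6,
                          int n_temps2 = 10, double kT2_high = 0.25,
                          double kT2_low = 0.05, int n_keep = 10) {
  Problem P(prob);
  Rng rng(seed);
  Trace tr;
  std::vector<int> a = random_assignment(P, rng);
  double E = P.total(a);
  std::vector<int> best = a; double bestE = E;
  tr.move.push_back(0.0); tr.best.push_back(bestE);
  long moves = 0; int qr1 = 0, qr2 = 0;
  std::vector<std::pair<double, std::vector<int> > > saved;  // energy-sorted

  if (P.movable.empty())
    return result_list(P, best, bestE, 0, 0, tr);

  #define NOTE_BEST(cand, candE) do { \
    if ((candE) < bestE) { bestE = (candE); best = (cand); \
      tr.move.push_back((double)moves); tr.best.push_back(bestE); } } while (0)

  #define QUENCH_RESTORE(counter) do { \
    std::vector<int> q = a; \
    quench_inplace(P, q); \
    double qe = P.total(q); \
    NOTE_BEST(q, qe); \
    bool dup = false; \
    for (size_t s_ = 0; s_ < saved.size(); ++s_) \
      if (saved[s_].second == q) { dup = true; break; } \
    if (!dup) { \
      saved.push_back(std::make_pair(qe, q)); \
      std::sort(saved.begin(), saved.end()); \
      if ((int)saved.size() > n_keep) saved.resize(n_keep); \
    } \
    ++counter; \
  } while (0)

  int M = moves_per_temp;
  int q1 = M / 4, q2 = M / 2, q3 = (3 * M) / 4;
  double f1 = std::pow(kT1_low / kT1_high, 1.0 / (n_temps1 - 1));
  double kT = kT1_high;
  for (int it = 0; it < n_temps1; ++it) {
    if (q1 == 0) QUENCH_RESTORE(qr1);
    if (q2 == 0) QUENCH_RESTORE(qr1);
    if (q3 == 0) QUENCH_RESTORE(qr1);
    for (int mv = 1; mv <= M; ++mv) {
      ++moves;
      metropolis_move(P, a, E, kT, rng, 0);
      NOTE_BEST(a, E);
      if (mv == q1 && q1 > 0) QUENCH_RESTORE(qr1);
      if (mv == q2 && q2 > 0 && q2 != q1) QUENCH_RESTORE(qr1);
      if (mv == q3 && q3 > 0 && q3 != q2 && q3 != q1) QUENCH_RESTORE(qr1);
    }
    E = P.total(a);
    kT *= f1;
  }
  // guarantee exactly 3 per temperature even on degenerate tiny M
  while (qr1 < 3 * n_temps1) QUENCH_RESTORE(qr1);

  int n_saved = (int)saved.size();
  double f2 = std::pow(kT2_low / kT2_high, 1.0 / (n_temps2 - 1));
  for (int t = 0; t < n_traj2; ++t) {
    a = saved[t < n_saved ? t : 0].second;   // reuse best if too few saved
    E = P.total(a);
    kT = kT2_high;
    for (int it = 0; it < n_temps2; ++it) {
      for (int mv = 0; mv < M; ++mv) {
        ++moves;
        metropolis_move(P, a, E, kT, rng, 0);
        NOTE_BEST(a, E);
      }
      E = P.total(a);
      std::vector<int> q = a;
      quench_inplace(P, q);
      double qe = P.total(q);
      NOTE_BEST(q, qe);
      ++qr2;
      kT *= f2;
    }
  }
  #undef QUENCH_RESTORE
  #undef NOTE_BEST
  List out = result_list(P, best, bestE, (double)moves, (double)qr1, tr);
  out["quench_restores_phase2"] = qr2;
  out["n_saved"] = n_saved;
  return out;
}

// Exact GMEC by enumeration; ties broken lexicographically by choice vector.
// [[Rcpp::export]]
List cpp_exhaustive(List prob) {
  Problem P(prob);
  double space = 1.0;
  for (int p = 0; p < P.n; ++p) space *= P.m[p];
  if (space > 1e7)
    stop("state space too large for exhaustive enumeration: %g assignments", space);
  std::vector<int> a(P.n, 0), best(P.n, 0);
  double bestE = P.total(a);
  for (;;) {
    int p = P.n - 1;
    while (p >= 0) {
      if (++a[p] < P.m[p]) break;
      a[p] = 0; --p;
    }
    if (p < 0) break;
    double E = P.total(a);
    if (E < bestE) { bestE = E; best = a; }
  }
  IntegerVector out(best.begin(), best.end());
  for (int i = 0; i < out.size(); ++i) out[i] += 1;
  return List::create(_["choice"] = out, _["energy"] = bestE);
}

// Fixed-temperature Metropolis sampler exposing the acceptance statistics of
// the same move kernel the annealers use.
// [[Rcpp::export]]
List cpp_metropolis_probe(List prob, IntegerVector start, double kT,
                          int n_moves, double seed) {
  Problem P(prob);
  Rng rng(seed);
  std::vector<int> a(start.begin(), start.end());
  for (int i = 0; i < P.n; ++i) a[i] -= 1;
  double E = P.total(a);
  long up_prop = 0, up_acc = 0;
  for (int mv = 0; mv < n_moves; ++mv) {
    double d;
    std::vector<int> before = a;
    bool acc = metropolis_move(P, a, E, kT, rng, &d);
    if (d > 0) { ++up_prop; if (acc) ++up_acc; }
  }
  return List::create(_["uphill_proposed"] = (double)up_prop,
                      _["uphill_accepted"] = (double)up_acc);
}

// 64-bit FNV-1a of a key string, folded to 53 bits so the value survives the
// R double boundary.  This is the seed-mixing primitive behind the
// order-independence contract: every (state, sequence, replicate) gets a
// stable stream regardless of evaluation order.
// [[Rcpp::export]]
double cpp_hash53(std::string key) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < key.size(); ++i) {
    h ^= (uint64_t)(unsigned char)key[i];
    h *= 1099511628211ULL;
  }
  // extra avalanche
  h ^= h >> 33; h *= 0xFF51AFD7ED558CCDULL; h ^= h >> 33;
  return (double)(h >> 11);
}
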