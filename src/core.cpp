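// Core Monte Carlo machinery: pair/total energy on the periodic lattice,
// single-particle and virtual-move dynamics, drive-biased state switches,
// the simulation loop, microstate census for exact-enumeration checks, and
// penalized piecewise-linear segmentation.
#include <Rcpp.h>
#include <random>
#include <queue>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// direction encoding shared with the R layer: 1=up, 2=down, 3=left, 4=right
static const int DIR_R[4] = {-1, 1, 0, 0};
static const int DIR_C[4] = {0, 0, -1, 1};

// ---------------------------------------------------------------------------
// RNG: mt19937_64 with explicit bit-to-double conversion so draws are
// reproducible independent of the standard library's distribution internals.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed ^ 0x9E3779B97F4A7C15ULL) {}
  // uniform in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1]
  double unif_open() { return 1.0 - unif(); }
  int randint(int n) { return (int)(unif() * n); }
};

static inline uint64_t as_seed(double s) {
  return (uint64_t)(int64_t)s;
}

// ---------------------------------------------------------------------------
// Interaction model: target adjacency lookup plus Eq. 1 branch logic.
struct Model {
  int L, N, M;
  double js, jw;
  bool directed;
  const int* adj;  // M*N*N, 1 if (i,j) nearest neighbours in target m
  const int* tdr;  // stored displacement (row) of j relative to i in target m
  const int* tdc;  // stored displacement (col)
};

static inline int wrapd(int d, int L) {
  d %= L;
  if (d < 0) d += L;
  if (d > L / 2) d -= L;
  return d;
}

static inline int wrap(int x, int L) {
  x %= L;
  if (x < 0) x += L;
  return x;
}

static inline bool in_target(const Model& m, int t, int i, int j, int dr, int dc) {
  size_t k = ((size_t)t * m.N + i) * m.N + j;
  if (!m.adj[k]) return false;
  if (!m.directed) return true;
  return m.tdr[k] == dr && m.tdc[k] == dc;
}

// Pair interaction for adjacent particles i, j at minimal displacement (dr,dc)
// from i to j, with internal states si, sj (0-based).
static inline double pair_e(const Model& m, int i, int j, int dr, int dc,
                            int si, int sj) {
  bool ai = in_target(m, si, i, j, dr, dc);
  if (si == sj) return ai ? m.js : m.jw;
  bool aj = in_target(m, sj, i, j, dr, dc);
  if (ai && aj) return m.js;
  if (ai || aj) return 0.5 * (m.js + m.jw);
  return m.jw;
}

// ---------------------------------------------------------------------------
// System state
struct Sys {
  int L, N;
  std::vector<int> r, c, s;  // per particle: row, col (0-based), state (0-based)
  std::vector<int> occ;      // site -> particle index or -1
  double E;
};

static Sys make_sys(int L, const IntegerVector& pr, const IntegerVector& pc,
                    const IntegerVector& ps) {
  Sys S;
  S.L = L;
  S.N = pr.size();
  S.r.assign(pr.begin(), pr.end());
  S.c.assign(pc.begin(), pc.end());
  S.s.assign(ps.begin(), ps.end());
  S.occ.assign((size_t)L * L, -1);
  for (int i = 0; i < S.N; ++i) {
    int site = S.r[i] * L + S.c[i];
    if (S.occ[site] >= 0) stop("two particles on one site");
    S.occ[site] = i;
  }
  S.E = 0.0;
  return S;
}

// O(N^2) from-scratch total energy; handles any L >= 2 (each unordered pair
// counted once from its minimal displacement).
static double total_energy_sys(const Model& m, const Sys& S) {
  double E = 0.0;
  for (int i = 0; i < S.N; ++i) {
    for (int j = i + 1; j < S.N; ++j) {
      int dr = wrapd(S.r[j] - S.r[i], S.L);
      int dc = wrapd(S.c[j] - S.c[i], S.L);
      if (std::abs(dr) + std::abs(dc) != 1) continue;
      E += pair_e(m, i, j, dr, dc, S.s[i], S.s[j]);
    }
  }
  return E;
}

// Sum of bond energies of particle i placed at (ri, ci) with state si,
// against current occupancy, skipping particle `skip`. Requires L >= 3 so the
// four neighbour sites are distinct.
static inline double local_energy(const Model& m, const Sys& S, int i,
                                  int ri, int ci, int si, int skip) {
  double e = 0.0;
  for (int d = 0; d < 4; ++d) {
    int nr = wrap(ri + DIR_R[d], S.L), nc = wrap(ci + DIR_C[d], S.L);
    int j = S.occ[nr * S.L + nc];
    if (j < 0 || j == i || j == skip) continue;
    e += pair_e(m, i, j, DIR_R[d], DIR_C[d], si, S.s[j]);
  }
  return e;
}

// ---------------------------------------------------------------------------
// SPMC: one attempted single-particle move. Returns the selected particle;
// *accepted reports the outcome.
static int spmc_attempt(const Model& m, Sys& S, Rng& rng, bool* accepted) {
  int p = rng.randint(S.N);
  int d = rng.randint(4);
  *accepted = false;
  int nr = wrap(S.r[p] + DIR_R[d], S.L), nc = wrap(S.c[p] + DIR_C[d], S.L);
  if (S.occ[nr * S.L + nc] >= 0) return p;  // destination occupied
  double e0 = local_energy(m, S, p, S.r[p], S.c[p], S.s[p], -1);
  double e1 = local_energy(m, S, p, nr, nc, S.s[p], -1);
  double dE = e1 - e0;
  if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
    S.occ[S.r[p] * S.L + S.c[p]] = -1;
    S.r[p] = nr; S.c[p] = nc;
    S.occ[nr * S.L + nc] = p;
    S.E += dE;
    *accepted = true;
  }
  return p;
}

// ---------------------------------------------------------------------------
// Drive bias for switching particle p from its current state to `snew`:
// +dmu if >= 2 current nearest neighbours hold snew, -dmu if >= 2 hold the
// current state; contributions are evaluated independently and summed.
static double drive_bias_sys(const Model& m, const Sys& S, int p, int snew,
                             double dmu) {
  int cnt_new = 0, cnt_cur = 0;
  for (int d = 0; d < 4; ++d) {
    int nr = wrap(S.r[p] + DIR_R[d], S.L), nc = wrap(S.c[p] + DIR_C[d], S.L);
    int j = S.occ[nr * S.L + nc];
    if (j < 0) continue;
    if (S.s[j] == snew) ++cnt_new;
    if (S.s[j] == S.s[p]) ++cnt_cur;
  }
  double b = 0.0;
  if (cnt_new >= 2) b += dmu;
  if (cnt_cur >= 2) b -= dmu;
  return b;
}

// One attempted state switch (excluding particle `exclude`).
static void switch_attempt(const Model& m, Sys& S, Rng& rng, double dmu,
                           int exclude) {
  if (m.M < 2) return;
  if (S.N == 1 && exclude == 0) return;
  int p = rng.randint(S.N);
  while (p == exclude) p = rng.randint(S.N);
  int snew = rng.randint(m.M - 1);
  if (snew >= S.s[p]) ++snew;
  double e0 = local_energy(m, S, p, S.r[p], S.c[p], S.s[p], -1);
  double e1 = local_energy(m, S, p, S.r[p], S.c[p], snew, -1);
  double dE = e1 - e0;
  double b = drive_bias_sys(m, S, p, snew, dmu);
  double arg = -dE + b;
  if (arg >= 0.0 || rng.unif() < std::exp(arg)) {
    S.s[p] = snew;
    S.E += dE;
  }
}

// ---------------------------------------------------------------------------
// VMMC

struct PairRec {
  int i, j;
  int dr0, dc0;    // displacement i -> j at test time (zeta geometry for
                   // zeta-adjacent pairs; eta geometry for eta-only pairs)
  bool zeta_adj;   // pair interacting before the move
  bool formed;
  bool hard_fwd;
  double p_fwd;    // forward link probability
};

struct MoveInfo {
  int seed = 0, dir = 0;
  long n_c = 0;
  std::vector<int> members;
  bool frustrated = false;
  bool reverse_zero = false;
  double dE = 0.0;
  double log_fwd_formed = 0.0, log_fwd_failed = 0.0;
  double log_rev_formed = 0.0, log_rev_failed = 0.0;
  double acc = 0.0;
};

// n_c = smallest integer strictly greater than 1/xi, xi ~ U(0,1]
static long draw_cutoff(Rng& rng) {
  double xi = rng.unif_open();
  return (long)std::floor(1.0 / xi) + 1L;
}

// Construct a cluster move seeded at p0 in direction d with cutoff n_c and
// evaluate its acceptance probability. Does not modify S.
static void vmmc_build(const Model& m, const Sys& S, Rng& rng, int p0, int d,
                       long n_c, MoveInfo& info) {
  const int L = S.L, N = S.N;
  info.seed = p0; info.dir = d; info.n_c = n_c;
  std::vector<char> inC((size_t)N, 0);
  std::vector<char> tested((size_t)N * N, 0);
  std::vector<PairRec> recs;
  std::vector<int>& members = info.members;
  members.clear();
  members.push_back(p0);
  inC[p0] = 1;
  std::queue<int> q;
  q.push(p0);

  if (1 > n_c) { info.frustrated = true; info.acc = 0.0; return; }

  while (!q.empty()) {
    int i = q.front(); q.pop();
    for (int e = 0; e < 4; ++e) {
      int nr = wrap(S.r[i] + DIR_R[e], L), nc = wrap(S.c[i] + DIR_C[e], L);
      int j = S.occ[nr * L + nc];
      if (j < 0 || inC[j]) continue;
      if (tested[(size_t)i * N + j]) continue;
      tested[(size_t)i * N + j] = tested[(size_t)j * N + i] = 1;
      double eps = pair_e(m, i, j, DIR_R[e], DIR_C[e], S.s[i], S.s[j]);
      int adr = wrapd(DIR_R[e] - DIR_R[d], L), adc = wrapd(DIR_C[e] - DIR_C[d], L);
      bool hard = (adr == 0 && adc == 0);  // j sits on i's destination
      double p;
      if (hard) {
        p = 1.0;
      } else {
        double epsp = (std::abs(adr) + std::abs(adc) == 1)
                          ? pair_e(m, i, j, adr, adc, S.s[i], S.s[j])
                          : 0.0;
        p = 1.0 - std::exp(-(epsp - eps));
        if (p < 0.0) p = 0.0;
      }
      bool formed = hard || (p > 0.0 && rng.unif() < p);
      PairRec rec; rec.i = i; rec.j = j; rec.dr0 = DIR_R[e]; rec.dc0 = DIR_C[e];
      rec.zeta_adj = true; rec.formed = formed; rec.hard_fwd = hard; rec.p_fwd = p;
      recs.push_back(rec);
      if (formed) {
        if ((long)members.size() + 1 > n_c) {
          info.frustrated = true;
          members.push_back(j);
          info.acc = 0.0;
          return;
        }
        inC[j] = 1;
        members.push_back(j);
        q.push(j);
      }
    }
  }

  // pairs interacting only in the virtually moved (eta) geometry:
  // occupants adjacent to a member's destination site that were not tested
  for (size_t k = 0; k < members.size(); ++k) {
    int i = members[k];
    int mr = wrap(S.r[i] + DIR_R[d], L), mc = wrap(S.c[i] + DIR_C[d], L);
    for (int e = 0; e < 4; ++e) {
      int nr = wrap(mr + DIR_R[e], L), nc = wrap(mc + DIR_C[e], L);
      int j = S.occ[nr * L + nc];
      if (j < 0 || inC[j]) continue;
      if (tested[(size_t)i * N + j]) continue;
      tested[(size_t)i * N + j] = tested[(size_t)j * N + i] = 1;
      PairRec rec; rec.i = i; rec.j = j; rec.dr0 = DIR_R[e]; rec.dc0 = DIR_C[e];
      rec.zeta_adj = false; rec.formed = false; rec.hard_fwd = false; rec.p_fwd = 0.0;
      recs.push_back(rec);
    }
  }

  // energy change: boundary bonds only (internal bonds ride along rigidly)
  double dE = 0.0;
  for (size_t k = 0; k < members.size(); ++k) {
    int i = members[k];
    for (int e = 0; e < 4; ++e) {
      int nr = wrap(S.r[i] + DIR_R[e], L), nc = wrap(S.c[i] + DIR_C[e], L);
      int j = S.occ[nr * L + nc];
      if (j >= 0 && !inC[j])
        dE -= pair_e(m, i, j, DIR_R[e], DIR_C[e], S.s[i], S.s[j]);
    }
    int mr = wrap(S.r[i] + DIR_R[d], L), mc = wrap(S.c[i] + DIR_C[d], L);
    for (int e = 0; e < 4; ++e) {
      int nr = wrap(mr + DIR_R[e], L), nc = wrap(mc + DIR_C[e], L);
      int j = S.occ[nr * L + nc];
      if (j >= 0 && !inC[j])
        dE += pair_e(m, i, j, DIR_R[e], DIR_C[e], S.s[i], S.s[j]);
    }
  }
  info.dE = dE;

  // reverse-move factors: same pair computation with the opposite direction
  // from the post-move geometry
  bool reject = false;
  for (size_t k = 0; k < recs.size() && !reject; ++k) {
    const PairRec& rec = recs[k];
    bool j_in = inC[rec.j] != 0;
    if (j_in) {
      // both moved: displacement unchanged; reverse virtual displacement r + d
      int adr = wrapd(rec.dr0 + DIR_R[d], L), adc = wrapd(rec.dc0 + DIR_C[d], L);
      bool hard_rev = (adr == 0 && adc == 0);
      double eps_rev = pair_e(m, rec.i, rec.j, rec.dr0, rec.dc0,
                              S.s[rec.i], S.s[rec.j]);
      double p_rev;
      if (hard_rev) {
        p_rev = 1.0;
      } else {
        double epsp = (std::abs(adr) + std::abs(adc) == 1)
                          ? pair_e(m, rec.i, rec.j, adr, adc, S.s[rec.i], S.s[rec.j])
                          : 0.0;
        p_rev = 1.0 - std::exp(-(epsp - eps_rev));
        if (p_rev < 0.0) p_rev = 0.0;
      }
      if (rec.formed) {
        if (p_rev <= 0.0) { reject = true; break; }
        info.log_fwd_formed += std::log(rec.p_fwd);
        info.log_rev_formed += std::log(p_rev);
      } else {
        // failed link internal to the final cluster
        if (1.0 - p_rev <= 0.0) { reject = true; break; }
        info.log_fwd_failed += std::log(1.0 - rec.p_fwd);
        info.log_rev_failed += std::log(1.0 - p_rev);
      }
    } else if (rec.zeta_adj) {
      // i moved, j did not: eta displacement r - d; reverse restores r
      int edr = wrapd(rec.dr0 - DIR_R[d], L), edc = wrapd(rec.dc0 - DIR_C[d], L);
      double eps = pair_e(m, rec.i, rec.j, rec.dr0, rec.dc0,
                          S.s[rec.i], S.s[rec.j]);
      double eps_rev = (std::abs(edr) + std::abs(edc) == 1)
                           ? pair_e(m, rec.i, rec.j, edr, edc, S.s[rec.i], S.s[rec.j])
                           : 0.0;
      double p_rev = 1.0 - std::exp(-(eps - eps_rev));
      if (p_rev < 0.0) p_rev = 0.0;
      double q_rev = 1.0 - p_rev;
      if (q_rev <= 0.0) { reject = true; break; }
      info.log_fwd_failed += std::log(1.0 - rec.p_fwd);
      info.log_rev_failed += std::log(q_rev);
    } else {
      // interacting only after the move: forward link auto-fails (q = 1)
      double eps_eta = pair_e(m, rec.i, rec.j, rec.dr0, rec.dc0,
                              S.s[rec.i], S.s[rec.j]);
      int bdr = wrapd(rec.dr0 + DIR_R[d], L), bdc = wrapd(rec.dc0 + DIR_C[d], L);
      double epsp_rev = (std::abs(bdr) + std::abs(bdc) == 1)
                            ? pair_e(m, rec.i, rec.j, bdr, bdc, S.s[rec.i], S.s[rec.j])
                            : 0.0;
      double p_rev = 1.0 - std::exp(-(epsp_rev - eps_eta));
      if (p_rev < 0.0) p_rev = 0.0;
      double q_rev = 1.0 - p_rev;
      if (q_rev <= 0.0) { reject = true; break; }
      info.log_rev_failed += std::log(q_rev);
    }
  }

  if (reject) {
    info.reverse_zero = true;
    info.acc = 0.0;
    return;
  }
  double logratio = (info.log_rev_formed - info.log_fwd_formed) +
                    (info.log_rev_failed - info.log_fwd_failed);
  double arg = -info.dE + logratio;
  double metro = arg >= 0.0 ? 1.0 : std::exp(arg);
  info.acc = metro / std::sqrt((double)members.size());
}

// One attempted VMMC move; returns the seed particle.
static int vmmc_attempt(const Model& m, Sys& S, Rng& rng, bool* accepted) {
  int p0 = rng.randint(S.N);
  int d = rng.randint(4);
  long n_c = draw_cutoff(rng);
  MoveInfo info;
  vmmc_build(m, S, rng, p0, d, n_c, info);
  *accepted = false;
  if (info.acc > 0.0 && rng.unif() < info.acc) {
    for (size_t k = 0; k < info.members.size(); ++k) {
      int i = info.members[k];
      S.occ[S.r[i] * S.L + S.c[i]] = -1;
    }
    for (size_t k = 0; k < info.members.size(); ++k) {
      int i = info.members[k];
      S.r[i] = wrap(S.r[i] + DIR_R[d], S.L);
      S.c[i] = wrap(S.c[i] + DIR_C[d], S.L);
      S.occ[S.r[i] * S.L + S.c[i]] = i;
    }
    S.E += info.dE;
    *accepted = true;
  }
  return p0;
}

// ---------------------------------------------------------------------------
// Max connected cluster of occupied sites (nearest-neighbour adjacency)
static int max_cluster_sys(const Sys& S) {
  if (S.N == 0) return 0;
  std::vector<char> seen((size_t)S.N, 0);
  int best = 0;
  std::vector<int> stack;
  for (int i = 0; i < S.N; ++i) {
    if (seen[i]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      ++size;
      for (int e = 0; e < 4; ++e) {
        int nr = wrap(S.r[u] + DIR_R[e], S.L), nc = wrap(S.c[u] + DIR_C[e], S.L);
        int j = S.occ[nr * S.L + nc];
        if (j >= 0 && !seen[j]) { seen[j] = 1; stack.push_back(j); }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Helpers to build Model from R arguments
static Model make_model(int L, int N, int M, double js, double jw, bool directed,
                        const IntegerVector& adj, const IntegerVector& tdr,
                        const IntegerVector& tdc) {
  Model m;
  m.L = L; m.N = N; m.M = M; m.js = js; m.jw = jw; m.directed = directed;
  m.adj = adj.begin(); m.tdr = tdr.begin(); m.tdc = tdc.begin();
  return m;
}

// [[Rcpp::export(name = ".cpp_pair_energy")]]
double cpp_pair_energy(int L, int N, int M, double js, double jw, bool directed,
                       IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                       int i, int j, int dr, int dc, int si, int sj) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  dr = wrapd(dr, L); dc = wrapd(dc, L);
  if (std::abs(dr) + std::abs(dc) != 1) stop("particles are not nearest neighbours");
  return pair_e(m, i, j, dr, dc, si, sj);
}

// [[Rcpp::export(name = ".cpp_total_energy")]]
double cpp_total_energy(int L, int N, int M, double js, double jw, bool directed,
                        IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                        IntegerVector pr, IntegerVector pc, IntegerVector ps) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  return total_energy_sys(m, S);
}

// Batch evaluation: rows of (positions, states) -> energies.
// [[Rcpp::export(name = ".cpp_energy_batch")]]
NumericVector cpp_energy_batch(int L, int N, int M, double js, double jw,
                               bool directed, IntegerVector adj,
                               IntegerVector tdr, IntegerVector tdc,
                               IntegerMatrix rows_r, IntegerMatrix rows_c,
                               IntegerMatrix rows_s) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  if (rows_r.ncol() != N || rows_c.ncol() != N || rows_s.ncol() != N)
    stop("placement matrices must have one column per particle");
  int n = rows_r.nrow();
  NumericVector out(n);
  Sys S;
  S.L = L; S.N = N;
  S.r.resize(N); S.c.resize(N); S.s.resize(N);
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < N; ++i) {
      S.r[i] = rows_r(k, i); S.c[i] = rows_c(k, i); S.s[i] = rows_s(k, i);
    }
    out[k] = total_energy_sys(m, S);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_max_cluster")]]
int cpp_max_cluster(int L, IntegerVector pr, IntegerVector pc) {
  IntegerVector ps(pr.size(), 0);
  Sys S = make_sys(L, pr, pc, ps);
  return max_cluster_sys(S);
}

// [[Rcpp::export(name = ".cpp_draw_cutoffs")]]
NumericVector cpp_draw_cutoffs(int n, double seed) {
  Rng rng(as_seed(seed));
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = (double)draw_cutoff(rng);
  return out;
}

// SPMC acceptance probe: deterministic acceptance probability for moving
// `particle` one site in `direction`.
// [[Rcpp::export(name = ".cpp_spmc_prob")]]
List cpp_spmc_prob(int L, int N, int M, double js, double jw, bool directed,
                   IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                   IntegerVector pr, IntegerVector pc, IntegerVector ps,
                   int particle, int direction) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  int d = direction;
  int nr = wrap(S.r[particle] + DIR_R[d], L), nc = wrap(S.c[particle] + DIR_C[d], L);
  bool blocked = S.occ[nr * L + nc] >= 0;
  double dE = NA_REAL, prob = 0.0;
  if (!blocked) {
    double e0 = local_energy(m, S, particle, S.r[particle], S.c[particle],
                             S.s[particle], -1);
    double e1 = local_energy(m, S, particle, nr, nc, S.s[particle], -1);
    dE = e1 - e0;
    prob = dE <= 0.0 ? 1.0 : std::exp(-dE);
  }
  return List::create(_["blocked"] = blocked, _["delta_e"] = dE,
                      _["prob"] = prob);
}

// State-switch acceptance probe.
// [[Rcpp::export(name = ".cpp_switch_prob")]]
List cpp_switch_prob(int L, int N, int M, double js, double jw, bool directed,
                     IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                     IntegerVector pr, IntegerVector pc, IntegerVector ps,
                     int particle, int new_state, double dmu) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  double e0 = local_energy(m, S, particle, S.r[particle], S.c[particle],
                           S.s[particle], -1);
  double e1 = local_energy(m, S, particle, S.r[particle], S.c[particle],
                           new_state, -1);
  double dE = e1 - e0;
  double b = drive_bias_sys(m, S, particle, new_state, dmu);
  double arg = -dE + b;
  double prob = arg >= 0.0 ? 1.0 : std::exp(arg);
  return List::create(_["delta_e"] = dE, _["bias"] = b, _["prob"] = prob);
}

// [[Rcpp::export(name = ".cpp_drive_bias")]]
double cpp_drive_bias(int L, int N, int M, double js, double jw, bool directed,
                      IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                      IntegerVector pr, IntegerVector pc, IntegerVector ps,
                      int particle, int new_state, double dmu) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  return drive_bias_sys(m, S, particle, new_state, dmu);
}

// Cluster-move probe: construct one tentative VMMC move and report its
// bookkeeping without touching the state.
// [[Rcpp::export(name = ".cpp_cluster_probe")]]
List cpp_cluster_probe(int L, int N, int M, double js, double jw, bool directed,
                       IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                       IntegerVector pr, IntegerVector pc, IntegerVector ps,
                       int seed_particle, int direction, double n_c,
                       double rng_seed) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  Rng rng(as_seed(rng_seed));
  MoveInfo info;
  vmmc_build(m, S, rng, seed_particle, direction, (long)n_c, info);
  IntegerVector members(info.members.begin(), info.members.end());
  return List::create(
      _["seed"] = info.seed, _["direction"] = info.dir,
      _["n_c"] = (double)info.n_c, _["members"] = members,
      _["n_members"] = (int)info.members.size(),
      _["frustrated"] = info.frustrated,
      _["reverse_zero"] = info.reverse_zero,
      _["delta_e"] = info.dE,
      _["log_fwd_formed"] = info.log_fwd_formed,
      _["log_fwd_failed"] = info.log_fwd_failed,
      _["log_rev_formed"] = info.log_rev_formed,
      _["log_rev_failed"] = info.log_rev_failed,
      _["acceptance"] = info.acc);
}

// ---------------------------------------------------------------------------
// Simulation loop: T iterations of (physical move, state switch), sampling the
// energy every n_mc iterations.
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(int L, int N, int M, double js, double jw, bool directed,
             IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
             IntegerVector pr, IntegerVector pc, IntegerVector ps,
             double n_steps, double n_mc, bool vmmc, double dmu,
             double threshold, bool halt, bool record_cluster, double seed) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  S.E = total_energy_sys(m, S);
  Rng rng(as_seed(seed));
  long long T = (long long)n_steps;
  long long bin = (long long)n_mc;
  if (bin < 1) stop("binning factor must be >= 1");
  long long n_sweeps = T / bin;
  std::vector<double> energies;
  std::vector<int> clusters;
  energies.reserve((size_t)n_sweeps);
  if (record_cluster) clusters.reserve((size_t)n_sweeps);
  double t_fas = NA_REAL;
  bool acc;
  for (long long t = 1; t <= T; ++t) {
    int mover = vmmc ? vmmc_attempt(m, S, rng, &acc)
                     : spmc_attempt(m, S, rng, &acc);
    switch_attempt(m, S, rng, dmu, mover);
    if (t % bin == 0) {
      energies.push_back(S.E);
      if (record_cluster) clusters.push_back(max_cluster_sys(S));
      if (ISNA(t_fas) && S.E <= threshold + 1e-9) {
        t_fas = (double)t;
        if (halt) break;
      }
    }
  }
  List out = List::create(
      _["energies"] = NumericVector(energies.begin(), energies.end()),
      _["max_cluster"] = record_cluster
                             ? (SEXP)IntegerVector(clusters.begin(), clusters.end())
                             : R_NilValue,
      _["t_fas"] = t_fas,
      _["r"] = IntegerVector(S.r.begin(), S.r.end()),
      _["c"] = IntegerVector(S.c.begin(), S.c.end()),
      _["s"] = IntegerVector(S.s.begin(), S.s.end()),
      _["energy"] = S.E,
      _["energy_check"] = total_energy_sys(m, S));
  return out;
}

// ---------------------------------------------------------------------------
// Microstate census for exact-enumeration equilibrium checks. Index encodes
// (site_i * M + state_i) per particle, mixed-radix with base L*L*M.
// [[Rcpp::export(name = ".cpp_census")]]
NumericVector cpp_census(int L, int N, int M, double js, double jw, bool directed,
                         IntegerVector adj, IntegerVector tdr, IntegerVector tdc,
                         IntegerVector pr, IntegerVector pc, IntegerVector ps,
                         double n_iter, double burn_in, bool vmmc, double dmu,
                         bool freeze_positions, double seed) {
  Model m = make_model(L, N, M, js, jw, directed, adj, tdr, tdc);
  Sys S = make_sys(L, pr, pc, ps);
  S.E = total_energy_sys(m, S);
  Rng rng(as_seed(seed));
  double base = (double)L * L * M;
  double total = 1.0;
  for (int i = 0; i < N; ++i) total *= base;
  if (total > 4e6) stop("microstate census space too large");
  NumericVector counts((R_xlen_t)total);
  long long T = (long long)n_iter, B = (long long)burn_in;
  bool acc;
  for (long long t = 1; t <= T + B; ++t) {
    int mover;
    if (freeze_positions) {
      mover = rng.randint(S.N);  // mover selected but held in place
    } else {
      mover = vmmc ? vmmc_attempt(m, S, rng, &acc)
                   : spmc_attempt(m, S, rng, &acc);
    }
    switch_attempt(m, S, rng, dmu, mover);
    if (t > B) {
      size_t idx = 0;
      for (int i = 0; i < N; ++i)
        idx = idx * (size_t)(L * L * M) + (size_t)(S.r[i] * L + S.c[i]) * M + S.s[i];
      counts[idx] += 1.0;
    }
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Penalized piecewise-linear segmentation by exact dynamic programming.
// Minimizes sum of per-segment linear-fit SSE + penalty per segment.
// Returns 0-based segment start indices.
// [[Rcpp::export(name = ".cpp_segment_dp")]]
IntegerVector cpp_segment_dp(NumericVector y, double penalty, int min_size) {
  int n = y.size();
  if (n < 2) stop("series must have length >= 2");
  if (min_size < 2) min_size = 2;
  std::vector<long double> S1(n + 1, 0.0L), S2(n + 1, 0.0L), S3(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    S1[i + 1] = S1[i] + (long double)y[i];
    S2[i + 1] = S2[i] + (long double)y[i] * y[i];
    S3[i + 1] = S3[i] + (long double)i * y[i];
  }
  auto cum_k = [](long long m) -> long double {
    // sum of 0..m and of squares 0..m
    return (long double)m * (m + 1) / 2.0L;
  };
  auto cum_k2 = [](long long m) -> long double {
    return (long double)m * (m + 1) * (2 * m + 1) / 6.0L;
  };
  auto cost = [&](int a, int b) -> double {
    int len = b - a + 1;
    if (len < 2) return 0.0;
    long double Sy = S1[b + 1] - S1[a];
    long double Syy = S2[b + 1] - S2[a];
    long double Sky = S3[b + 1] - S3[a];
    long double Sk = cum_k(b) - (a > 0 ? cum_k(a - 1) : 0.0L);
    long double Skk = cum_k2(b) - (a > 0 ? cum_k2(a - 1) : 0.0L);
    long double Sxx = Skk - Sk * Sk / len;
    long double Sxy = Sky - Sk * Sy / len;
    long double Syc = Syy - Sy * Sy / len;
    long double sse = Syc - (Sxx > 1e-12L ? Sxy * Sxy / Sxx : 0.0L);
    if (sse < 0.0L) sse = 0.0L;
    return (double)sse;
  };
  const double INF = R_PosInf;
  std::vector<double> F(n + 1, INF);
  std::vector<int> back(n + 1, -1);
  F[0] = 0.0;
  for (int t = min_size; t <= n; ++t) {
    for (int s = 0; s + min_size <= t; ++s) {
      if (!R_FINITE(F[s])) continue;
      double cand = F[s] + cost(s, t - 1) + penalty;
      if (cand < F[t]) { F[t] = cand; back[t] = s; }
    }
  }
  if (!R_FINITE(F[n])) {
    // series shorter than 2*min_size collapses to a single segment
    return IntegerVector::create(0);
  }
  std::vector<int> starts;
  int t = n;
  while (t > 0) { starts.push_back(back[t]); t = back[t]; }
  std::reverse(starts.begin(), starts.end());
  return IntegerVector(starts.begin(), starts.end());
}
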