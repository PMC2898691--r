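// Structured-coalescent / ancestral-recombination-graph simulator with
// MS unit conventions: time in units of 4*N_ref generations, population
// sizes relative to N_ref, theta = 4*N_ref*mu*L and rho = 4*N_ref*r per
// locus, infinite-sites mutation on the continuous interval (0,1).
// In these units a pair of lineages in a population of relative size x
// coalesces at rate 2/x and mutations fall at rate theta per unit of
// branch length, giving E[S] = theta * a_{n-1} and E[pi] = theta.
//
// Demographic events (looking backwards in time):
//   type 0: set relative size of population `pop` to `param`
//   type 1: move every lineage of population `pop` into population `param`
//
// Lineages carry ordered lists of ancestral segments; each segment points
// to the node that roots the sample subtree for that genomic interval and
// stores the number of samples below it.  Segments that reach the full
// sample count (local MRCA) are discarded.  Edges (child node -> parent
// node over an interval, with the child's birth time and the coalescence
// time) accumulate the branch "area" on which mutations are dropped.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <stdexcept>

namespace {

struct Seg {
  double l, r;
  int node;
  int nsamp;
};

typedef std::vector<Seg> Lineage;

struct Edge {
  int child, parent;
  double l, r, tc, tp;
};

// splitmix64: deterministic per-locus stream derivation from a master seed
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

class Rng {
 public:
  explicit Rng(uint64_t seed) : s_(splitmix64(seed ^ 0xDA3E39CB94B95BDBULL)) {
    if (s_ == 0) s_ = 0x853C49E6748FEA9BULL;
  }
  // xorshift64* core
  uint64_t next() {
    s_ ^= s_ >> 12;
    s_ ^= s_ << 25;
    s_ ^= s_ >> 27;
    return s_ * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // (0,1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  double rexp(double rate) { return -std::log(unif()) / rate; }
  int rpois(double lambda) {
    // inversion for small lambda, normal-ish rejection fallback via PTRS
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do {
        ++k;
        p *= unif();
      } while (p > L);
      return k - 1;
    }
    // split recursively to stay in the inversion regime (lambda here is
    // modest in practice: theta/2 * tree area)
    int a = rpois(lambda / 2.0);
    int b = rpois(lambda - lambda / 2.0);
    return a + b;
  }
  int runif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }

 private:
  uint64_t s_;
};

inline double lin_span(const Lineage& L) {
  return L.back().r - L.front().l;
}

// append a segment to `out`, merging with the previous one when contiguous
// and identical in node and sample count
inline void push_seg(Lineage& out, double l, double r, int node, int nsamp) {
  if (!out.empty() && out.back().r == l && out.back().node == node &&
      out.back().nsamp == nsamp) {
    out.back().r = r;
  } else {
    Seg s;
    s.l = l; s.r = r; s.node = node; s.nsamp = nsamp;
    out.push_back(s);
  }
}

inline void push_edge(std::vector<Edge>& edges, int child, int parent,
                      double l, double r, double tc, double tp) {
  if (!edges.empty()) {
    Edge& e = edges.back();
    if (e.child == child && e.parent == parent && e.r == l && e.tc == tc &&
        e.tp == tp) {
      e.r = r;
      return;
    }
  }
  Edge e;
  e.child = child; e.parent = parent; e.l = l; e.r = r; e.tc = tc; e.tp = tp;
  edges.push_back(e);
}

struct SimOut {
  std::vector<double> pos;            // sorted positions in (0,1)
  std::vector<std::vector<int> > carriers;  // per mutation: sample ids
  int n;
};

void merge_lineages(const Lineage& A, const Lineage& B, double t, int n,
                    std::vector<double>& ntime, std::vector<Edge>& edges,
                    Lineage& out) {
  out.clear();
  int u = -1;  // parent node, created lazily on first overlap
  size_t ia = 0, ib = 0;
  double cur = std::min(A.front().l, B.front().l);
  while (ia < A.size() || ib < B.size()) {
    bool inA = ia < A.size() && A[ia].l <= cur && cur < A[ia].r;
    bool inB = ib < B.size() && B[ib].l <= cur && cur < B[ib].r;
    // next boundary strictly greater than cur
    double nxt = 2.0;
    if (ia < A.size()) nxt = std::min(nxt, A[ia].l > cur ? A[ia].l : A[ia].r);
    if (ib < B.size()) nxt = std::min(nxt, B[ib].l > cur ? B[ib].l : B[ib].r);
    if (inA && inB) {
      if (u < 0) {
        u = static_cast<int>(ntime.size());
        ntime.push_back(t);
      }
      push_edge(edges, A[ia].node, u, cur, nxt, ntime[A[ia].node], t);
      push_edge(edges, B[ib].node, u, cur, nxt, ntime[B[ib].node], t);
      int cnt = A[ia].nsamp + B[ib].nsamp;
      if (cnt < n) push_seg(out, cur, nxt, u, cnt);
    } else if (inA) {
      push_seg(out, cur, nxt, A[ia].node, A[ia].nsamp);
    } else if (inB) {
      push_seg(out, cur, nxt, B[ib].node, B[ib].nsamp);
    }
    cur = nxt;
    if (ia < A.size() && A[ia].r <= cur) ++ia;
    if (ib < B.size() && B[ib].r <= cur) ++ib;
    if (cur >= 2.0) break;  // safety; cannot happen with well-formed input
  }
}

SimOut simulate_arg(const std::vector<int>& nsamp, double theta, double rho,
                    std::vector<double> size, const std::vector<double>& evTime,
                    const std::vector<int>& evType, const std::vector<int>& evPop,
                    const std::vector<double>& evParam, Rng& rng) {
  const int npop = static_cast<int>(nsamp.size());
  int n = 0;
  for (int k = 0; k < npop; ++k) n += nsamp[k];
  if (n < 2) throw std::runtime_error("need at least two haplotypes in total");
  for (int k = 0; k < npop; ++k)
    if (size[k] <= 0.0) throw std::runtime_error("population sizes must be > 0");

  std::vector<std::vector<Lineage> > pops(npop);
  std::vector<double> ntime;
  ntime.reserve(4 * n);
  int id = 0;
  for (int k = 0; k < npop; ++k) {
    for (int j = 0; j < nsamp[k]; ++j) {
      Lineage L(1);
      L[0].l = 0.0; L[0].r = 1.0; L[0].node = id; L[0].nsamp = 1;
      pops[k].push_back(L);
      ntime.push_back(0.0);
      ++id;
    }
  }

  std::vector<Edge> edges;
  edges.reserve(16 * n);
  double t = 0.0;
  size_t ev = 0;
  const size_t nev = evTime.size();
  long iter = 0;
  Lineage merged;

  for (;;) {
    size_t nlin = 0;
    for (int k = 0; k < npop; ++k) nlin += pops[k].size();
    if (nlin == 0) break;
    if (++iter > 2000000L)
      throw std::runtime_error("coalescent did not complete (event cap reached)");

    double coalRate = 0.0, recRate = 0.0;
    std::vector<double> popCoal(npop, 0.0);
    for (int k = 0; k < npop; ++k) {
      double nk = static_cast<double>(pops[k].size());
      popCoal[k] = nk * (nk - 1.0) / size[k];
      coalRate += popCoal[k];
      if (rho > 0.0)
        for (size_t i = 0; i < pops[k].size(); ++i)
          recRate += rho * lin_span(pops[k][i]);
    }
    double total = coalRate + recRate;

    if (total <= 0.0) {
      if (ev < nev) {
        t = evTime[ev];
      } else {
        throw std::runtime_error(
            "no coalescence possible: isolated populations with no join event");
      }
    } else {
      double dt = rng.rexp(total);
      if (ev < nev && t + dt >= evTime[ev]) {
        t = evTime[ev];
      } else {
        t += dt;
        if (rng.unif() * total < coalRate) {
          // coalescence: choose population, then an unordered lineage pair
          double u = rng.unif() * coalRate;
          int k = 0;
          while (k < npop - 1 && u >= popCoal[k]) { u -= popCoal[k]; ++k; }
          int m = static_cast<int>(pops[k].size());
          if (m < 2) continue;  // numerically impossible draw; redraw
          int i = rng.runif_int(m);
          int j = rng.runif_int(m - 1);
          if (j >= i) ++j;
          merge_lineages(pops[k][i], pops[k][j], t, n, ntime, edges, merged);
          if (i < j) std::swap(i, j);  // remove larger index first
          pops[k].erase(pops[k].begin() + i);
          pops[k].erase(pops[k].begin() + j);
          if (!merged.empty()) pops[k].push_back(merged);
        } else {
          // recombination: lineage weighted by ancestral span
          double u = rng.unif() * recRate;
          int k = 0; size_t i = 0; bool found = false;
          for (k = 0; k < npop && !found; ++k)
            for (i = 0; i < pops[k].size(); ++i) {
              double w = rho * lin_span(pops[k][i]);
              if (u < w) { found = true; break; }
              u -= w;
            }
          if (found) {
            --k;  // loop incremented past
            Lineage& L = pops[k][i];
            double y = rng.unif(L.front().l, L.back().r);
            Lineage left, right;
            for (size_t s = 0; s < L.size(); ++s) {
              if (L[s].r <= y) left.push_back(L[s]);
              else if (L[s].l >= y) right.push_back(L[s]);
              else {
                Seg a = L[s], b = L[s];
                a.r = y; b.l = y;
                left.push_back(a);
                right.push_back(b);
              }
            }
            if (!left.empty() && !right.empty()) {
              pops[k][i] = left;
              pops[k].push_back(right);
            }
          }
        }
        continue;
      }
    }

    // apply the pending demographic event at time t
    if (ev < nev) {
      int k = evPop[ev];
      if (evType[ev] == 0) {
        size[k] = evParam[ev];
      } else {
        int dest = static_cast<int>(evParam[ev]);
        for (size_t i = 0; i < pops[k].size(); ++i)
          pops[dest].push_back(pops[k][i]);
        pops[k].clear();
      }
      ++ev;
    }
  }

  // drop mutations on the recorded edges
  double area = 0.0;
  std::vector<double> cum(edges.size());
  for (size_t e = 0; e < edges.size(); ++e) {
    area += (edges[e].tp - edges[e].tc) * (edges[e].r - edges[e].l);
    cum[e] = area;
  }
  SimOut out;
  out.n = n;
  int nmut = (theta > 0.0 && area > 0.0) ? rng.rpois(theta * area) : 0;
  if (nmut == 0) return out;

  // child index for descendant traversal
  std::vector<std::vector<int> > childIdx(ntime.size());
  for (size_t e = 0; e < edges.size(); ++e)
    childIdx[edges[e].parent].push_back(static_cast<int>(e));

  out.pos.reserve(nmut);
  out.carriers.reserve(nmut);
  std::vector<int> stack;
  for (int m = 0; m < nmut; ++m) {
    double u = rng.unif() * area;
    size_t e = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (e >= edges.size()) e = edges.size() - 1;
    double p = rng.unif(edges[e].l, edges[e].r);
    std::vector<int> carr;
    stack.clear();
    stack.push_back(edges[e].child);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < n) {
        carr.push_back(v);
        continue;
      }
      const std::vector<int>& kids = childIdx[v];
      for (size_t q = 0; q < kids.size(); ++q) {
        const Edge& ke = edges[kids[q]];
        if (ke.l <= p && p < ke.r) stack.push_back(ke.child);
      }
    }
    out.pos.push_back(p);
    out.carriers.push_back(carr);
  }
  // sort mutations by position
  std::vector<size_t> ord(out.pos.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return out.pos[a] < out.pos[b]; });
  SimOut sorted;
  sorted.n = n;
  sorted.pos.reserve(ord.size());
  sorted.carriers.reserve(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    sorted.pos.push_back(out.pos[ord[i]]);
    sorted.carriers.push_back(out.carriers[ord[i]]);
  }
  return sorted;
}

}  // namespace

// [[Rcpp::export(name = ".simLocusCpp")]]
Rcpp::List sim_locus_cpp(Rcpp::IntegerVector nsamp, double theta, double rho,
                         Rcpp::NumericVector sizes, Rcpp::NumericVector evTime,
                         Rcpp::IntegerVector evType, Rcpp::IntegerVector evPop,
                         Rcpp::NumericVector evParam, double seed) {
  std::vector<int> ns(nsamp.begin(), nsamp.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> et(evTime.begin(), evTime.end());
  std::vector<int> ety(evType.begin(), evType.end());
  std::vector<int> epo(evPop.begin(), evPop.end());
  std::vector<double> epa(evParam.begin(), evParam.end());
  Rng rng(static_cast<uint64_t>(seed));
  SimOut s = simulate_arg(ns, theta, rho, sz, et, ety, epo, epa, rng);
  int S = static_cast<int>(s.pos.size());
  Rcpp::IntegerMatrix G(S, s.n);  // sites x haplotypes, 1 = derived
  for (int m = 0; m < S; ++m)
    for (size_t j = 0; j < s.carriers[m].size(); ++j)
      G(m, s.carriers[m][j]) = 1;
  return Rcpp::List::create(Rcpp::Named("positions") = Rcpp::wrap(s.pos),
                            Rcpp::Named("genotypes") = G);
}

// Same as .simLocusCpp but with the per-locus stream derived from a master
// seed and 0-based locus index, matching the derivation used by
// .simSummaryCpp, so a dataset rendered locus-by-locus is identical to the
// one summarised by the fast path.
// [[Rcpp::export(name = ".simLocusMasterCpp")]]
Rcpp::List sim_locus_master_cpp(Rcpp::IntegerVector nsamp, double theta,
                                double rho, Rcpp::NumericVector sizes,
                                Rcpp::NumericVector evTime,
                                Rcpp::IntegerVector evType,
                                Rcpp::IntegerVector evPop,
                                Rcpp::NumericVector evParam, double seed,
                                int locusIndex) {
  uint64_t ls = splitmix64(static_cast<uint64_t>(seed)) ^
                splitmix64(0x1000000ULL + static_cast<uint64_t>(locusIndex));
  return sim_locus_cpp(nsamp, theta, rho, sizes, evTime, evType, evPop,
                       evParam, static_cast<double>(ls % 9007199254740992ULL));
}

// Simulate a full multi-locus dataset and return only the eight pooled ABC
// summary statistics (weed = population 0, progenitor = population 1):
//   pooled theta_pi per kb, S weed, S progenitor, fixed, private weed,
//   private progenitor, shared, S union.
// [[Rcpp::export(name = ".simSummaryCpp")]]
Rcpp::NumericVector sim_summary_cpp(int nWeed, int nProg,
                                    Rcpp::NumericVector lengths,
                                    double thetaPerSite, double rhoOverTheta,
                                    Rcpp::NumericVector sizes,
                                    Rcpp::NumericVector evTime,
                                    Rcpp::IntegerVector evType,
                                    Rcpp::IntegerVector evPop,
                                    Rcpp::NumericVector evParam, double seed) {
  std::vector<int> ns(2);
  ns[0] = nWeed; ns[1] = nProg;
  std::vector<double> et(evTime.begin(), evTime.end());
  std::vector<int> ety(evType.begin(), evType.end());
  std::vector<int> epo(evPop.begin(), evPop.end());
  std::vector<double> epa(evParam.begin(), evParam.end());
  const int n = nWeed + nProg;
  double piSum = 0.0, Ltot = 0.0;
  long sW = 0, sP = 0, fixed = 0, privW = 0, privP = 0, shared = 0, sU = 0;
  for (int loc = 0; loc < lengths.size(); ++loc) {
    double L = lengths[loc];
    Ltot += L;
    double theta = thetaPerSite * L;
    uint64_t ls = splitmix64(static_cast<uint64_t>(seed)) ^
                  splitmix64(0x1000000ULL + static_cast<uint64_t>(loc));
    Rng rng(ls % 9007199254740992ULL);  // same stream as .simLocusMasterCpp
    std::vector<double> sz(sizes.begin(), sizes.end());
    SimOut s = simulate_arg(ns, theta, rhoOverTheta * theta, sz, et, ety, epo,
                            epa, rng);
    for (size_t m = 0; m < s.pos.size(); ++m) {
      int dw = 0, dp = 0;
      const std::vector<int>& carr = s.carriers[m];
      for (size_t j = 0; j < carr.size(); ++j) {
        if (carr[j] < nWeed) ++dw; else ++dp;
      }
      int d = dw + dp;
      if (d == 0 || d == n) continue;  // not segregating in the sample
      ++sU;
      piSum += 2.0 * d * (n - d) / (static_cast<double>(n) * (n - 1));
      bool polyW = dw > 0 && dw < nWeed;
      bool polyP = dp > 0 && dp < nProg;
      if (polyW) ++sW;
      if (polyP) ++sP;
      if (polyW && polyP) ++shared;
      else if (polyW) ++privW;
      else if (polyP) ++privP;
      else ++fixed;  // both monomorphic for different alleles
    }
  }
  Rcpp::NumericVector out(8);
  out[0] = piSum / Ltot * 1000.0;
  out[1] = sW; out[2] = sP; out[3] = fixed;
  out[4] = privW; out[5] = privP; out[6] = shared; out[7] = sU;
  out.names() = Rcpp::CharacterVector::create(
      "pooledPi", "sWeed", "sProgenitor", "fixed", "privateWeed",
      "privateProgenitor", "shared", "sUnion");
  return out;
}
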