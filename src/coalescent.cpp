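// Structured-coalescent engine: multi-population isolation-with-migration
// demographies with piecewise-constant sizes. Time is measured backward in
// generations; population sizes are diploid Ne. All entry points take an
// integer seed; per-replicate substreams are derived by counter so that
// window k is reproducible in isolation.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const int MAXPOP = 8;

// ---------------------------------------------------------------------------
// RNG: mt19937_64 engine (bit-reproducible per the C++ standard) with our own
// variate transforms, so results do not depend on the stdlib's distributions.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(splitmix64(seed)) {}
  double u01() { return (eng() >> 11) * (1.0 / 9007199254740992.0); } // [0,1)
  double uo01() {
    double u;
    do { u = u01(); } while (u <= 0.0);
    return u;
  }
  double rexp(double rate) { return -std::log(uo01()) / rate; }
  int runif_int(int n) { // uniform on {0,...,n-1}
    int k = (int)(u01() * n);
    return k >= n ? n - 1 : k;
  }
  // Poisson: Knuth multiplication below 30, Hormann PTRS above.
  int rpois(double mu) {
    if (mu <= 0.0) return 0;
    if (mu < 30.0) {
      double L = std::exp(-mu), p = 1.0;
      int k = 0;
      do { ++k; p *= u01(); } while (p > L);
      return k - 1;
    }
    const double b = 0.931 + 2.53 * std::sqrt(mu);
    const double a = -0.059 + 0.02483 * b;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    const double v_r = 0.9277 - 3.6224 / (b - 2.0);
    const double lmu = std::log(mu);
    while (true) {
      double U = u01() - 0.5;
      double V = uo01();
      double us = 0.5 - std::fabs(U);
      double k = std::floor((2.0 * a / us + b) * U + mu + 0.43);
      if (us >= 0.07 && V <= v_r) return (int)k;
      if (k < 0.0 || (us < 0.013 && V > us)) continue;
      if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          k * lmu - mu - std::lgamma(k + 1.0))
        return (int)k;
    }
  }
};

// ---------------------------------------------------------------------------
// Demography as flattened by the R side (see .sim_model() in R/coalescent-sim.R)

struct Demog {
  int npop;
  std::vector<int> nsam;        // haplotypes sampled per population
  std::vector<double> Ne0;      // present-day diploid sizes
  std::vector<double> mig0;     // backward rates, row-major [i*npop+j]: i -> j
  std::vector<double> ev_time;  // sorted ascending; split(0) before resize(1) at ties
  std::vector<int> ev_type;     // 0 split, 1 resize
  std::vector<int> ev_pop;
  std::vector<int> ev_dest;     // split target
  std::vector<double> ev_size;  // resize value
};

static Demog demog_from_list(const List& m) {
  Demog d;
  d.nsam = as<std::vector<int>>(m["nsam"]);
  d.npop = (int)d.nsam.size();
  if (d.npop > MAXPOP) stop("at most %d populations supported", MAXPOP);
  d.Ne0 = as<std::vector<double>>(m["ne"]);
  NumericMatrix mig = m["mig_backward"];
  d.mig0.assign(d.npop * d.npop, 0.0);
  for (int i = 0; i < d.npop; ++i)
    for (int j = 0; j < d.npop; ++j)
      if (i != j) d.mig0[i * d.npop + j] = mig(i, j);
  d.ev_time = as<std::vector<double>>(m["ev_time"]);
  d.ev_type = as<std::vector<int>>(m["ev_type"]);
  d.ev_pop  = as<std::vector<int>>(m["ev_pop"]);
  d.ev_dest = as<std::vector<int>>(m["ev_dest"]);
  d.ev_size = as<std::vector<double>>(m["ev_size"]);
  for (double ne : d.Ne0) if (!(ne > 0) || !std::isfinite(ne)) stop("non-finite or non-positive Ne");
  return d;
}

struct Lin {
  double birth;
  int pop;
  int node;                     // tree node id (tips first)
  std::array<int, MAXPOP> cnt;  // sampled descendants per population
  uint64_t mask;                // descendant tip bitmask
};

struct Branch {
  double len;
  std::array<int, MAXPOP> cnt;
  uint64_t mask;
};

struct TreeRec {            // optional topology recording
  std::vector<int> parent, child;
  std::vector<double> blen;
  std::vector<double> node_time;
};

// One replicate of the structured coalescent. Fills `branches` (every branch
// below the grand MRCA) and returns the TMRCA.
static double sim_rep(const Demog& D, Rng& rng, std::vector<Branch>& branches,
                      TreeRec* rec = nullptr) {
  const int P = D.npop;
  std::vector<double> Ne = D.Ne0;
  std::vector<double> mig = D.mig0;
  std::vector<Lin> lin;
  int tip = 0, ntips = 0;
  for (int p = 0; p < P; ++p) ntips += D.nsam[p];
  if (ntips > 64) stop("at most 64 haplotypes supported");
  lin.reserve(ntips);
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < D.nsam[p]; ++i) {
      Lin l;
      l.birth = 0.0; l.pop = p; l.node = tip;
      l.cnt.fill(0); l.cnt[p] = 1;
      l.mask = 1ULL << tip;
      ++tip;
      lin.push_back(l);
    }
  int next_node = ntips;
  if (rec) {
    rec->parent.clear(); rec->child.clear(); rec->blen.clear();
    rec->node_time.assign(ntips, 0.0);
  }
  branches.clear();
  branches.reserve(2 * ntips);

  std::vector<double> rowmig(P, 0.0);
  auto recalc_rows = [&]() {
    for (int p = 0; p < P; ++p) {
      double s = 0.0;
      for (int j = 0; j < P; ++j) if (j != p) s += mig[p * P + j];
      rowmig[p] = s;
    }
  };
  recalc_rows();

  double t = 0.0;
  size_t ei = 0;
  int guard = 0;
  while ((int)lin.size() > 1) {
    if (++guard > 100000000) stop("coalescent did not complete (runaway event loop)");
    int k[MAXPOP] = {0};
    for (const Lin& l : lin) ++k[l.pop];
    double crate[MAXPOP], ctot = 0.0, mtot = 0.0;
    for (int p = 0; p < P; ++p) {
      crate[p] = k[p] > 1 ? k[p] * (k[p] - 1.0) / (4.0 * Ne[p]) : 0.0;
      ctot += crate[p];
      mtot += k[p] * rowmig[p];
    }
    double tot = ctot + mtot;
    double tev = ei < D.ev_time.size() ? D.ev_time[ei] : R_PosInf;
    double dt = tot > 0.0 ? rng.rexp(tot) : R_PosInf;
    if (t + dt >= tev) {
      t = tev;
      if (D.ev_type[ei] == 0) { // split: ev_pop merges into ev_dest
        int p = D.ev_pop[ei], dd = D.ev_dest[ei];
        for (Lin& l : lin) if (l.pop == p) l.pop = dd;
        for (int j = 0; j < P; ++j) { mig[p * P + j] = 0.0; mig[j * P + p] = 0.0; }
        recalc_rows();
      } else {
        Ne[D.ev_pop[ei]] = D.ev_size[ei];
      }
      ++ei;
      continue;
    }
    if (!std::isfinite(dt))
      stop("lineages cannot coalesce: populations never share an ancestor");
    t += dt;
    double u = rng.u01() * tot;
    if (u < ctot) { // coalescence
      int p = 0; double acc = 0.0;
      for (; p < P - 1; ++p) { acc += crate[p]; if (u < acc) break; }
      int i1 = rng.runif_int(k[p]), i2;
      do { i2 = rng.runif_int(k[p]); } while (i2 == i1);
      int a = -1, b = -1, c = 0;
      for (size_t x = 0; x < lin.size(); ++x)
        if (lin[x].pop == p) {
          if (c == i1) a = (int)x;
          if (c == i2) b = (int)x;
          ++c;
        }
      Branch ba; ba.len = t - lin[a].birth; ba.cnt = lin[a].cnt; ba.mask = lin[a].mask;
      Branch bb; bb.len = t - lin[b].birth; bb.cnt = lin[b].cnt; bb.mask = lin[b].mask;
      branches.push_back(ba);
      branches.push_back(bb);
      Lin nl;
      nl.birth = t; nl.pop = p; nl.node = next_node++;
      for (int q = 0; q < P; ++q) nl.cnt[q] = lin[a].cnt[q] + lin[b].cnt[q];
      nl.mask = lin[a].mask | lin[b].mask;
      if (rec) {
        rec->node_time.push_back(t);
        rec->parent.push_back(nl.node); rec->child.push_back(lin[a].node); rec->blen.push_back(ba.len);
        rec->parent.push_back(nl.node); rec->child.push_back(lin[b].node); rec->blen.push_back(bb.len);
      }
      if (a > b) std::swap(a, b);
      lin[a] = nl;
      lin.erase(lin.begin() + b);
    } else { // migration
      double v = u - ctot;
      int p = 0; double acc = 0.0;
      for (; p < P - 1; ++p) { acc += k[p] * rowmig[p]; if (v < acc) break; }
      int idx = rng.runif_int(k[p]), a = -1, c = 0;
      for (size_t x = 0; x < lin.size(); ++x)
        if (lin[x].pop == p) { if (c == idx) { a = (int)x; break; } ++c; }
      if (a < 0) continue; // rounding race at a just-processed event; redraw
      double w = rng.u01() * rowmig[p];
      int j = -1; double a2 = 0.0;
      for (int jj = 0; jj < P; ++jj) {
        if (jj == p) continue;
        a2 += mig[p * P + jj];
        if (w < a2) { j = jj; break; }
      }
      if (j < 0) for (int jj = P - 1; jj >= 0; --jj) if (jj != p && mig[p * P + jj] > 0) { j = jj; break; }
      if (j >= 0) lin[a].pop = j;
    }
  }
  return t;
}

static inline long sfs_index(const std::array<int, MAXPOP>& cnt,
                             const std::vector<long>& stride, int P) {
  long idx = 0;
  for (int p = 0; p < P; ++p) idx += (long)cnt[p] * stride[p];
  return idx;
}

static std::vector<long> sfs_strides(const std::vector<int>& nsam) {
  // column-major: matches array(v, dim = nsam + 1) on the R side
  std::vector<long> s(nsam.size());
  long acc = 1;
  for (size_t p = 0; p < nsam.size(); ++p) { s[p] = acc; acc *= nsam[p] + 1; }
  return s;
}

// ---------------------------------------------------------------------------
// Expected joint SFS from branch lengths, plus per-rep genealogy summaries.

// [[Rcpp::export]]
List sim_sfs_branch_cpp(List model, int nreps, double seed) {
  Demog D = demog_from_list(model);
  std::vector<long> stride = sfs_strides(D.nsam);
  long ncell = 1;
  for (int n : D.nsam) ncell *= n + 1;
  NumericVector sfs(ncell);
  NumericVector tmrca(nreps), tlen(nreps);
  std::vector<Branch> br;
  for (int r = 0; r < nreps; ++r) {
    Rng rng(splitmix64((uint64_t)seed) ^ (0xA5A5A5A5ULL + (uint64_t)r));
    tmrca[r] = sim_rep(D, rng, br);
    double tot = 0.0;
    for (const Branch& b : br) {
      sfs[sfs_index(b.cnt, stride, D.npop)] += b.len;
      tot += b.len;
    }
    tlen[r] = tot;
  }
  return List::create(_["sfs"] = sfs, _["tmrca"] = tmrca, _["total_length"] = tlen);
}

// ---------------------------------------------------------------------------
// Observed joint-SFS counts: per window one genealogy, Poisson mutations per
// branch tallied into derived-count classes (infinite sites, count level).

// [[Rcpp::export]]
List sim_sfs_count_cpp(List model, int nwindows, double window_bp,
                       double mu_per_gen, double seed) {
  Demog D = demog_from_list(model);
  std::vector<long> stride = sfs_strides(D.nsam);
  long ncell = 1;
  for (int n : D.nsam) ncell *= n + 1;
  NumericVector sfs(ncell);
  NumericVector S(nwindows);
  std::vector<Branch> br;
  for (int w = 0; w < nwindows; ++w) {
    Rng rng(splitmix64((uint64_t)seed) ^ (0xC3C3C3C3ULL + (uint64_t)w * 0x9E3779B9ULL));
    sim_rep(D, rng, br);
    double s = 0.0;
    for (const Branch& b : br) {
      int nm = rng.rpois(b.len * mu_per_gen * window_bp);
      if (nm > 0) {
        sfs[sfs_index(b.cnt, stride, D.npop)] += nm;
        s += nm;
      }
    }
    S[w] = s;
  }
  return List::create(_["sfs"] = sfs, _["S"] = S);
}

// ---------------------------------------------------------------------------
// Sequence windows: one non-recombining genealogy per window, infinite-sites
// mutations at distinct integer positions; returns haplotype 0/1 matrices.

// [[Rcpp::export]]
List sim_windows_cpp(List model, int nwindows, double window_bp,
                     double mu_per_gen, double seed) {
  Demog D = demog_from_list(model);
  int ntips = 0;
  for (int n : D.nsam) ntips += n;
  List out(nwindows);
  std::vector<Branch> br;
  int L = (int)window_bp;
  for (int w = 0; w < nwindows; ++w) {
    Rng rng(splitmix64((uint64_t)seed) ^ (0xC3C3C3C3ULL + (uint64_t)w * 0x9E3779B9ULL));
    double tm = sim_rep(D, rng, br);
    double tot = 0.0;
    std::vector<double> cum(br.size());
    for (size_t i = 0; i < br.size(); ++i) { tot += br[i].len; cum[i] = tot; }
    int nmut = rng.rpois(tot * mu_per_gen * window_bp);
    if (nmut > 0.9 * window_bp)
      stop("window diversity saturates the infinite-sites model: %d mutations on %d bp; "
           "reduce Ne/mu or enlarge windows", nmut, L);
    std::vector<std::pair<int, uint64_t>> sites;
    sites.reserve(nmut);
    std::unordered_set<int> used;
    for (int m = 0; m < nmut; ++m) {
      double u = rng.u01() * tot;
      size_t b = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (b >= br.size()) b = br.size() - 1;
      int pos;
      do { pos = rng.runif_int(L); } while (used.count(pos));
      used.insert(pos);
      sites.push_back(std::make_pair(pos, br[b].mask));
    }
    std::sort(sites.begin(), sites.end());
    IntegerVector pos(nmut);
    IntegerMatrix geno(ntips, nmut);
    for (int s = 0; s < nmut; ++s) {
      pos[s] = sites[s].first;
      for (int tipi = 0; tipi < ntips; ++tipi)
        geno(tipi, s) = (int)((sites[s].second >> tipi) & 1ULL);
    }
    out[w] = List::create(_["pos"] = pos, _["geno"] = geno,
                          _["tmrca"] = tm, _["total_length"] = tot);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Single genealogy with topology, for simulate_genealogy().

// [[Rcpp::export]]
List sim_tree_cpp(List model, double seed) {
  Demog D = demog_from_list(model);
  std::vector<Branch> br;
  TreeRec rec;
  Rng rng(splitmix64((uint64_t)seed) ^ 0xA5A5A5A5ULL);
  double tm = sim_rep(D, rng, br, &rec);
  double tot = 0.0;
  for (const Branch& b : br) tot += b.len;
  IntegerVector tip_pop;
  for (int p = 0; p < D.npop; ++p)
    for (int i = 0; i < D.nsam[p]; ++i) tip_pop.push_back(p + 1);
  return List::create(_["parent"] = wrap(rec.parent), _["child"] = wrap(rec.child),
                      _["blen"] = wrap(rec.blen), _["node_time"] = wrap(rec.node_time),
                      _["tip_pop"] = tip_pop, _["tmrca"] = tm, _["total_length"] = tot);
}

// ---------------------------------------------------------------------------
// SMC recombination along a window, single panmictic population.
// Marginal genealogies change by detach/re-coalesce at sequence breakpoints;
// mutations dropped segment by segment (infinite sites).

struct SmcTree {
  int n;                         // tips
  std::vector<int> parent;       // -1 for root
  std::vector<double> time;      // node times
  int root;
  double total_len() const {
    double s = 0.0;
    for (int v = 0; v < (int)parent.size(); ++v)
      if (parent[v] >= 0) s += time[parent[v]] - time[v];
    return s;
  }
};

static void smc_masks(const SmcTree& T, std::vector<uint64_t>& mask) {
  int N = (int)T.parent.size();
  mask.assign(N, 0ULL);
  for (int v = 0; v < T.n; ++v) mask[v] = 1ULL << v;
  // accumulate tips upward; process nodes in time order (children precede parents)
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return T.time[a] < T.time[b]; });
  for (int i = 0; i < N; ++i) {
    int v = ord[i];
    if (T.parent[v] >= 0) mask[T.parent[v]] |= mask[v];
  }
}

// [[Rcpp::export]]
List sim_smc_window_cpp(int n, double Ne, double rho_window, double window_bp,
                        double mu_per_gen, double seed) {
  if (n < 2 || n > 64) stop("n must be in [2, 64]");
  Rng rng(splitmix64((uint64_t)seed) ^ 0x5C5C5C5CULL);
  int L = (int)window_bp;
  double c_per_bp = rho_window / (4.0 * Ne * window_bp); // rho = 4*Ne*c per window

  // initial (leftmost) Kingman tree
  SmcTree T;
  T.n = n;
  T.parent.assign(2 * n - 1, -1);
  T.time.assign(2 * n - 1, 0.0);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  double t = 0.0;
  int nxt = n;
  while ((int)act.size() > 1) {
    int k = (int)act.size();
    t += rng.rexp(k * (k - 1.0) / (4.0 * Ne));
    int i = rng.runif_int(k), j;
    do { j = rng.runif_int(k); } while (j == i);
    T.time[nxt] = t;
    T.parent[act[i]] = nxt;
    T.parent[act[j]] = nxt;
    if (i > j) std::swap(i, j);
    act[i] = nxt;
    act.erase(act.begin() + j);
    ++nxt;
  }
  T.root = 2 * n - 2;

  std::vector<uint64_t> mask;
  std::vector<std::pair<int, uint64_t>> sites;
  std::unordered_set<int> used;
  double pos = 0.0;
  int guard = 0;
  while (pos < window_bp) {
    if (++guard > 5000000) stop("SMC loop guard tripped");
    double tl = T.total_len();
    double dist = c_per_bp > 0 ? rng.rexp(tl * c_per_bp) : R_PosInf;
    double seg_end = std::min(window_bp, pos + dist);
    double seg_len = seg_end - pos;
    // mutations on this segment
    int nmut = rng.rpois(tl * mu_per_gen * seg_len);
    if ((int)used.size() + nmut > 0.9 * window_bp)
      stop("window diversity saturates the infinite-sites model");
    if (nmut > 0) {
      smc_masks(T, mask);
      // cumulative branch lengths over non-root nodes
      std::vector<int> nodes;
      std::vector<double> cum;
      double acc = 0.0;
      for (int v = 0; v < (int)T.parent.size(); ++v)
        if (T.parent[v] >= 0) {
          acc += T.time[T.parent[v]] - T.time[v];
          nodes.push_back(v);
          cum.push_back(acc);
        }
      for (int m = 0; m < nmut; ++m) {
        double u = rng.u01() * acc;
        size_t b = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
        if (b >= nodes.size()) b = nodes.size() - 1;
        int p;
        do { p = (int)pos + rng.runif_int(std::max(1, (int)seg_len)); } while (p >= L || used.count(p));
        used.insert(p);
        sites.push_back(std::make_pair(p, mask[nodes[b]]));
      }
    }
    pos = seg_end;
    if (pos >= window_bp) break;
    // recombination: cut uniformly on the tree, detach, re-coalesce
    double u = rng.u01() * tl, acc2 = 0.0;
    int v = -1;
    for (int x = 0; x < (int)T.parent.size(); ++x)
      if (T.parent[x] >= 0) {
        double bl = T.time[T.parent[x]] - T.time[x];
        acc2 += bl;
        if (u < acc2) { v = x; break; }
      }
    if (v < 0) continue;
    int par = T.parent[v];
    double tcut = T.time[par] - (acc2 - u); // uniform on the branch
    // sibling of v under par
    int sib = -1;
    for (int x = 0; x < (int)T.parent.size(); ++x)
      if (x != v && T.parent[x] == par) { sib = x; break; }
    int grand = T.parent[par];
    // remove par: sibling attaches to grandparent (or becomes root)
    T.parent[v] = -1;
    T.parent[sib] = grand;
    if (grand < 0) T.root = sib;
    // lineages of the remaining tree crossing time s: nodes u with parent
    // (after removal) whose interval [time[u], time[parent]] spans s, plus the
    // root lineage extending to infinity.
    // piecewise-constant re-coalescence from tcut
    double s = tcut;
    int attach = -1;
    double t_at = 0.0;
    while (attach < 0) {
      // collect crossing lineages at time s and the next node time above s
      double tnext = R_PosInf;
      std::vector<int> cross;
      for (int x = 0; x < (int)T.parent.size(); ++x) {
        if (x == v || x == par) continue;
        double lo = T.time[x];
        double hi = (T.parent[x] >= 0) ? T.time[T.parent[x]] : R_PosInf;
        if (x == T.root) hi = R_PosInf;
        if (T.parent[x] < 0 && x != T.root) continue; // detached par slot
        if (lo <= s && hi > s) cross.push_back(x);
        if (lo > s && lo < tnext) tnext = lo;
      }
      int k = (int)cross.size();
      if (k == 0) stop("SMC internal error: no lineage to re-coalesce with");
      double w = rng.rexp(k / (2.0 * Ne));
      if (s + w < tnext) {
        t_at = s + w;
        attach = cross[rng.runif_int(k)];
      } else {
        s = tnext;
      }
    }
    // reuse node `par` as the new internal node at t_at
    int tgt_parent = (attach == T.root) ? -1 : T.parent[attach];
    T.time[par] = t_at;
    T.parent[v] = par;
    T.parent[attach] = par;
    T.parent[par] = tgt_parent;
    if (tgt_parent < 0) T.root = par;
  }

  std::sort(sites.begin(), sites.end());
  int S = (int)sites.size();
  IntegerVector spos(S);
  IntegerMatrix geno(n, S);
  for (int s2 = 0; s2 < S; ++s2) {
    spos[s2] = sites[s2].first;
    for (int tipi = 0; tipi < n; ++tipi)
      geno(tipi, s2) = (int)((sites[s2].second >> tipi) & 1ULL);
  }
  return List::create(_["pos"] = spos, _["geno"] = geno);
}
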