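// Coalescent simulator for the four-population fire-ant scenario and the
// DIYABC-style summary statistics computed on its output. The reference
// table for ABC needs tens of thousands of simulated datasets, which is why
// this stage is compiled; the R-level summary_stats module implements the
// same statistics independently and the two are cross-checked in tests.
//
// Backward-in-time model (times in generations before sampling):
//   demes: 0 = native source (N_N1), 1 = second native cluster (N_N2),
//          2 = introduced (N_I).
//   deme 2 has size N_I on (0, T_I - T_B), size N_F on (T_I - T_B, T_I),
//   and merges into deme 0 at T_I. Deme 1 merges into deme 0 at T_D,
//   after which the ancestral population keeps size N_N1.
// One biallelic SNP per locus: a single mutation is placed on the genealogy
// with probability proportional to branch length (every branch lies below
// the grand MRCA, so the pooled sample is always polymorphic).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  // splitmix64: stable across platforms, good enough statistically here
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double expo(double rate) { return -std::log(1.0 - unif()) / rate; }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Tree {
  std::vector<double> time;
  std::vector<int> left, right, parent;
  int n_tips;
  explicit Tree(int tips) : time(2 * tips - 1, 0.0), left(2 * tips - 1, -1),
                            right(2 * tips - 1, -1), parent(2 * tips - 1, -1),
                            n_tips(tips) {}
};

// Coalesce within demes until `t_end` (or fully coalesced); lineages per
// deme are node indices into `tree`. `next_node` is the next free index.
void run_epoch(Tree &tree, std::vector<std::vector<int>> &demes,
               const std::vector<double> &sizes, double t0, double t_end,
               double &t, int &next_node, Rng &rng) {
  t = t0;
  for (;;) {
    double total = 0.0;
    std::vector<double> rate(demes.size(), 0.0);
    for (size_t d = 0; d < demes.size(); ++d) {
      double k = (double)demes[d].size();
      if (k >= 2.0 && sizes[d] > 0)
        rate[d] = k * (k - 1.0) / 2.0 / (2.0 * sizes[d]);
      total += rate[d];
    }
    if (total <= 0.0) { t = t_end; return; }
    double dt = rng.expo(total);
    if (t + dt >= t_end) { t = t_end; return; }
    t += dt;
    double u = rng.unif() * total;
    size_t d = 0;
    for (; d + 1 < demes.size(); ++d) { if (u < rate[d]) break; u -= rate[d]; }
    int k = (int)demes[d].size();
    int i = rng.below(k);
    int j = rng.below(k - 1);
    if (j >= i) ++j;
    int a = demes[d][i], b = demes[d][j];
    int p = next_node++;
    tree.time[p] = t;
    tree.left[p] = a; tree.right[p] = b;
    tree.parent[a] = p; tree.parent[b] = p;
    if (i > j) std::swap(i, j);
    demes[d][i] = p;
    demes[d].erase(demes[d].begin() + j);
  }
}

// Simulate one locus genealogy; returns derived-allele indicator per gene
// copy (tips ordered: deme0 copies, deme1 copies, deme2 copies).
void sim_locus(const std::vector<double> &par, int c0, int c1, int c2,
               Rng &rng, std::vector<int> &derived) {
  const double N1 = par[0], N2 = par[1], NF = par[2], NI = par[3];
  const double TD = par[4], TI = par[5], TB = par[6];
  int tips = c0 + c1 + c2;
  Tree tree(tips);
  std::vector<std::vector<int>> demes(3);
  for (int i = 0; i < c0; ++i) demes[0].push_back(i);
  for (int i = 0; i < c1; ++i) demes[1].push_back(c0 + i);
  for (int i = 0; i < c2; ++i) demes[2].push_back(c0 + c1 + i);
  int next_node = tips;
  double t = 0.0;

  std::vector<double> sizes = {N1, N2, NI};
  run_epoch(tree, demes, sizes, 0.0, TI - TB, t, next_node, rng);
  sizes[2] = NF;
  run_epoch(tree, demes, sizes, t, TI, t, next_node, rng);
  // introduced lineages join the native source
  demes[0].insert(demes[0].end(), demes[2].begin(), demes[2].end());
  demes[2].clear();
  run_epoch(tree, demes, sizes, t, TD, t, next_node, rng);
  demes[0].insert(demes[0].end(), demes[1].begin(), demes[1].end());
  demes[1].clear();
  run_epoch(tree, demes, sizes, t, 1e300, t, next_node, rng);

  // choose mutated branch proportional to length (root excluded)
  int root = 2 * tips - 2;
  double L = 0.0;
  for (int v = 0; v < root; ++v) L += tree.time[tree.parent[v]] - tree.time[v];
  double target = rng.unif() * L, acc = 0.0;
  int mut = root - 1;
  for (int v = 0; v < root; ++v) {
    acc += tree.time[tree.parent[v]] - tree.time[v];
    if (acc >= target) { mut = v; break; }
  }
  // mark tips below the mutated branch
  derived.assign(tips, 0);
  std::vector<int> stack = {mut};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < tips) { derived[v] = 1; continue; }
    stack.push_back(tree.left[v]);
    stack.push_back(tree.right[v]);
  }
}

// DIYABC-style within-population statistics from allele counts.
// cnt: derived-allele genotype sum per locus; ncop = 2 * n_ind.
void within_stats(const std::vector<int> &cnt, int ncop, bool reduced,
                  std::vector<double> &out) {
  int L = (int)cnt.size();
  double n = (double)ncop;
  int n_mono = 0;
  double sum_all = 0.0, sum_poly = 0.0, sumsq_poly = 0.0;
  int n_poly = 0;
  for (int j = 0; j < L; ++j) {
    bool mono = (cnt[j] == 0 || cnt[j] == ncop);
    double p = cnt[j] / n;
    double h = mono ? 0.0 : n / (n - 1.0) * (1.0 - p * p - (1.0 - p) * (1.0 - p));
    sum_all += h;
    if (mono) { ++n_mono; } else { ++n_poly; sum_poly += h; sumsq_poly += h * h; }
  }
  double prop_mono = L ? (double)n_mono / L : NA_REAL;
  double mean_all = L ? sum_all / L : NA_REAL;
  if (reduced) { out.push_back(prop_mono); out.push_back(mean_all); return; }
  double mean_poly = n_poly ? sum_poly / n_poly : 0.0;
  double var_poly = n_poly > 1
    ? (sumsq_poly - n_poly * mean_poly * mean_poly) / (n_poly - 1.0) : 0.0;
  out.push_back(prop_mono);
  out.push_back(mean_poly);
  out.push_back(var_poly > 0 ? var_poly : 0.0);
  out.push_back(mean_all);
}

// Weir-Cockerham pair statistics from per-locus genotype matrices (no
// missing data in simulated output). geno arrays: per locus x individual.
void pair_stats(const std::vector<std::vector<int>> &ga,
                const std::vector<std::vector<int>> &gb,
                std::vector<double> &out) {
  int L = (int)ga.size();
  double sum_a = 0.0, sum_abc = 0.0;
  std::vector<double> fst;
  fst.reserve(L);
  for (int j = 0; j < L; ++j) {
    double n1 = (double)ga[j].size(), n2 = (double)gb[j].size();
    double s1 = 0, het1 = 0, s2c = 0, het2 = 0;
    for (int x : ga[j]) { s1 += x; het1 += (x == 1); }
    for (int x : gb[j]) { s2c += x; het2 += (x == 1); }
    double p1 = s1 / (2 * n1), p2 = s2c / (2 * n2);
    double h1 = het1 / n1, h2 = het2 / n2;
    const double r = 2.0;
    double nbar = (n1 + n2) / r;
    double nc = (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1.0);
    double pbar = (n1 * p1 + n2 * p2) / (r * nbar);
    double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                 n2 * (p2 - pbar) * (p2 - pbar)) / ((r - 1.0) * nbar);
    double hbar = (n1 * h1 + n2 * h2) / (r * nbar);
    double a = (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1));
    double b = (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar);
    double c = hbar / 2;
    double abc = a + b + c;
    if (abc != 0.0 && std::isfinite(abc)) {
      sum_a += a; sum_abc += abc;
      fst.push_back(a / abc);
    }
  }
  double mean_fst = sum_abc != 0.0 ? sum_a / sum_abc : NA_REAL;
  int nf = (int)fst.size();
  int n_null = 0, n_pos = 0;
  double sp = 0.0, spsq = 0.0;
  for (double f : fst) {
    if (f <= 0) ++n_null; else { ++n_pos; sp += f; spsq += f * f; }
  }
  double prop_null = nf ? (double)n_null / nf : NA_REAL;
  double mean_pos = n_pos ? sp / n_pos : 0.0;
  double var_pos = n_pos > 1 ? (spsq - n_pos * mean_pos * mean_pos) / (n_pos - 1.0) : 0.0;
  out.push_back(mean_fst);
  out.push_back(prop_null);
  out.push_back(mean_pos);
  out.push_back(var_pos > 0 ? var_pos : 0.0);
}

void stats_from_derived(const std::vector<std::vector<int>> &geno,
                        int d0, int d1, int d2, std::vector<double> &out) {
  int L = (int)geno.size();
  std::vector<int> cnt0(L), cnt1(L), cnt2(L);
  std::vector<std::vector<int>> g0(L), g1(L), g2(L);
  for (int j = 0; j < L; ++j) {
    g0[j].assign(geno[j].begin(), geno[j].begin() + d0);
    g1[j].assign(geno[j].begin() + d0, geno[j].begin() + d0 + d1);
    g2[j].assign(geno[j].begin() + d0 + d1, geno[j].end());
    int c0 = 0, c1 = 0, c2 = 0;
    for (int x : g0[j]) c0 += x;
    for (int x : g1[j]) c1 += x;
    for (int x : g2[j]) c2 += x;
    cnt0[j] = c0; cnt1[j] = c1; cnt2[j] = c2;
  }
  within_stats(cnt0, 2 * d0, false, out);
  within_stats(cnt1, 2 * d1, false, out);
  within_stats(cnt2, 2 * d2, true, out);
  pair_stats(g0, g1, out);
  pair_stats(g0, g2, out);
}

// Simulate one dataset -> per-locus genotype vectors (individuals in deme
// order, genotype = derived-allele count in {0,1,2}).
void sim_dataset(const std::vector<double> &par, int d0, int d1, int d2,
                 int n_loci, Rng &rng, std::vector<std::vector<int>> &geno) {
  int c0 = 2 * d0, c1 = 2 * d1, c2 = 2 * d2;
  geno.assign(n_loci, std::vector<int>());
  std::vector<int> derived;
  for (int l = 0; l < n_loci; ++l) {
    sim_locus(par, c0, c1, c2, rng, derived);
    std::vector<int> &g = geno[l];
    g.resize(d0 + d1 + d2);
    for (int i = 0; i < d0 + d1 + d2; ++i)
      g[i] = derived[2 * i] + derived[2 * i + 1];
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sim_genotypes(NumericVector params, int n1, int n2, int ni,
                                int n_loci, double seed) {
  std::vector<double> par(params.begin(), params.end());
  Rng rng((uint64_t)seed);
  std::vector<std::vector<int>> geno;
  sim_dataset(par, n1, n2, ni, n_loci, rng, geno);
  IntegerMatrix out(n1 + n2 + ni, n_loci);
  for (int j = 0; j < n_loci; ++j)
    for (int i = 0; i < n1 + n2 + ni; ++i)
      out(i, j) = geno[j][i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_reference_table_stats(NumericMatrix param_table,
                                        int n1, int n2, int ni, int n_loci,
                                        double seed) {
  int S = param_table.nrow();
  NumericMatrix out(S, 18);
  for (int s = 0; s < S; ++s) {
    std::vector<double> par(7);
    for (int k = 0; k < 7; ++k) par[k] = param_table(s, k);
    Rng rng((uint64_t)seed + 0x51ed2701ULL * (uint64_t)(s + 1));
    std::vector<std::vector<int>> geno;
    sim_dataset(par, n1, n2, ni, n_loci, rng, geno);
    std::vector<double> st;
    st.reserve(18);
    stats_from_derived(geno, n1, n2, ni, st);
    for (int k = 0; k < 18; ++k) out(s, k) = st[k];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stats_from_genotypes(IntegerMatrix geno, int n1, int n2,
                                       int ni) {
  int L = geno.ncol();
  std::vector<std::vector<int>> g(L);
  for (int j = 0; j < L; ++j) {
    g[j].resize(geno.nrow());
    for (int i = 0; i < geno.nrow(); ++i) g[j][i] = geno(i, j);
  }
  std::vector<double> st;
  st.reserve(18);
  stats_from_derived(g, n1, n2, ni, st);
  return NumericVector(st.begin(), st.end());
}
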