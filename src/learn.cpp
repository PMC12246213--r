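#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Family BIC scores for every (node, parent set) pair on complete binary data.
//
// Counting strategy: one pass builds the full joint contingency table over all
// n variables; for each node v a depth-first recursion over parent-set masks
// marginalises one variable at a time, so the total counting work per node is
// sum_{S} 2^{|S|+1} = O(3^n) instead of O(2^n) per family.
//
// Score convention: maximised multinomial log-likelihood (natural log,
// 0*log 0 = 0) minus (log N / 2) * 2^{|parents|} * (r - 1) with r = 2.
// Parent configurations never observed contribute 0 likelihood but still
// count in the penalty dimension.

static double family_score_from_table(const std::vector<double>& t, int npar,
                                      double half_log_n) {
  const size_t q = (size_t)1 << npar;
  double ll = 0.0;
  for (size_t j = 0; j < q; ++j) {
    double n0 = t[j], n1 = t[j | q], nj = n0 + n1;
    if (n0 > 0) ll += n0 * std::log(n0 / nj);
    if (n1 > 0) ll += n1 * std::log(n1 / nj);
  }
  return ll - half_log_n * (double)q;
}

static void score_rec(unsigned int mask, const std::vector<double>& table,
                      unsigned int limit_bit, int v, int n, int max_parents,
                      const std::vector<int>& pos2var, double half_log_n,
                      NumericMatrix& S) {
  // bits of `mask` index the *other* variables (positions 0..n-2)
  int npar = 0;
  for (unsigned int m = mask; m; m &= m - 1) ++npar;
  if (max_parents < 0 || npar <= max_parents) {
    // expand position-mask into a mask over actual variable indices
    unsigned int full = 0;
    {
      unsigned int m = mask;
      while (m) {
        int p = __builtin_ctz(m);
        full |= 1u << pos2var[p];
        m &= m - 1;
      }
    }
    S(full, v) = family_score_from_table(table, npar, half_log_n);
  }
  // recurse on subsets, removing bits in decreasing order along each path
  // so that every subset is visited exactly once
  unsigned int m = mask;
  while (m) {
    int b = __builtin_ctz(m);
    m &= m - 1;
    if ((unsigned int)b >= limit_bit) break;
    // index k of bit b among the sorted bits of mask
    int k = 0;
    for (unsigned int mm = mask & ((1u << b) - 1); mm; mm &= mm - 1) ++k;
    const size_t len = table.size();
    std::vector<double> child(len >> 1, 0.0);
    const size_t lowmask = ((size_t)1 << k) - 1;
    for (size_t idx = 0; idx < len; ++idx) {
      size_t low = idx & lowmask;
      size_t rest = (idx >> (k + 1)) << k;
      child[low | rest] += table[idx];
    }
    score_rec(mask ^ (1u << b), child, (unsigned int)b, v, n, max_parents,
              pos2var, half_log_n, S);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_family_scores(IntegerMatrix X, int max_parents) {
  const int N = X.nrow(), n = X.ncol();
  if (n < 1 || n > 20) stop("number of variables must be in 1..20");
  const size_t ncell = (size_t)1 << n;
  std::vector<double> joint(ncell, 0.0);
  for (int r = 0; r < N; ++r) {
    unsigned int m = 0;
    for (int j = 0; j < n; ++j) {
      int x = X(r, j);
      if (x != 0 && x != 1) stop("data must be complete and binary");
      if (x) m |= 1u << j;
    }
    joint[m] += 1.0;
  }
  const double half_log_n = 0.5 * std::log((double)N);
  NumericMatrix S(ncell, n);
  std::fill(S.begin(), S.end(), R_NegInf);
  for (int v = 0; v < n; ++v) {
    std::vector<int> pos2var(n - 1);
    int p = 0;
    for (int j = 0; j < n; ++j) if (j != v) pos2var[p++] = j;
    // base table over (others ascending, v as top bit)
    std::vector<double> base(ncell, 0.0);
    for (size_t m = 0; m < ncell; ++m) {
      if (joint[m] == 0.0) continue;
      size_t cfg = 0;
      for (int k = 0; k < n - 1; ++k)
        if (m & ((size_t)1 << pos2var[k])) cfg |= (size_t)1 << k;
      if (m & ((size_t)1 << v)) cfg |= (size_t)1 << (n - 1);
      base[cfg] += joint[m];
    }
    score_rec((1u << (n - 1)) - 1u, base, (unsigned int)n, v, n, max_parents,
              pos2var, half_log_n, S);
  }
  return S;
}

// Exact structure search over the family-score table:
//  (i)   best parent set within every candidate variable subset,
//  (ii)  best-sink dynamic program over variable subsets,
//  (iii) order reconstruction.
// Ties are broken toward smaller parent sets, then toward the
// lowest-index variable (callers pass variables in name order).
// [[Rcpp::export]]
List cpp_learn_exact(NumericMatrix S) {
  const int n = S.ncol();
  const size_t nmask = (size_t)S.nrow();
  if (nmask != ((size_t)1 << n)) stop("score matrix has wrong shape");
  // bss[v][mask] = best score of any parent set inside `mask` (mask excl. v)
  std::vector<std::vector<double> > bss(n, std::vector<double>(nmask, R_NegInf));
  std::vector<std::vector<unsigned int> > bps(n, std::vector<unsigned int>(nmask, 0));
  for (int v = 0; v < n; ++v) {
    for (size_t mask = 0; mask < nmask; ++mask) {
      if (mask & ((size_t)1 << v)) continue;
      double best = R_NegInf;
      unsigned int arg = 0;
      for (size_t m = mask; m; m &= m - 1) {
        int b = __builtin_ctz((unsigned int)m);
        size_t sub = mask ^ ((size_t)1 << b);
        if (bss[v][sub] > best) { best = bss[v][sub]; arg = bps[v][sub]; }
      }
      double own = S(mask, v);
      if (own > best) { best = own; arg = (unsigned int)mask; }
      bss[v][mask] = best;
      bps[v][mask] = arg;
    }
    if (!R_FINITE(bss[v][0]))
      stop("empty-parent family score must be finite");
  }
  std::vector<double> M(nmask, R_NegInf);
  std::vector<int> sink(nmask, -1);
  M[0] = 0.0;
  for (size_t mask = 1; mask < nmask; ++mask) {
    for (size_t m = mask; m; m &= m - 1) {
      int s = __builtin_ctz((unsigned int)m);
      size_t rest = mask ^ ((size_t)1 << s);
      double cand = M[rest] + bss[s][rest];
      if (cand > M[mask]) { M[mask] = cand; sink[mask] = s; }
    }
  }
  List parents(n);
  size_t mask = nmask - 1;
  while (mask) {
    int s = sink[mask];
    size_t rest = mask ^ ((size_t)1 << s);
    unsigned int pm = bps[s][rest];
    IntegerVector pv;
    for (unsigned int m = pm; m; m &= m - 1)
      pv.push_back(__builtin_ctz(m));   // 0-based variable indices
    parents[s] = pv;
    mask = rest;
  }
  return List::create(_["parents"] = parents,
                      _["score"] = M[nmask - 1]);
}
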