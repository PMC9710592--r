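#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Node numbering convention used throughout: leaves are 1..n, internal node
// created by (1-based) merge row t is n+t, the root is 2n-1.

static inline double dpow(double x, double p) {
  return p == 2.0 ? x * x : std::pow(x, p);
}

// One side of a tanglegram: child columns of the merge table plus a scratch
// leaf-order buffer kept in sync by compute_order().
struct Side {
  std::vector<int> c1, c2, order, stack;
  int n, nrow;

  void init(const IntegerMatrix& mg, int n_) {
    n = n_;
    nrow = mg.nrow();
    c1.resize(nrow);
    c2.resize(nrow);
    for (int t = 0; t < nrow; ++t) { c1[t] = mg(t, 0); c2[t] = mg(t, 1); }
    order.resize(n);
    stack.reserve(2 * n);
  }

  // depth-first from the root, column-1 child before column-2 child
  void compute_order() {
    stack.clear();
    stack.push_back(n + nrow);
    int pos = 0;
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      if (node <= n) {
        order[pos++] = node;
      } else {
        int t = node - n - 1;
        stack.push_back(c2[t]);
        stack.push_back(c1[t]);
      }
    }
  }

  void swap_row(int t0) { std::swap(c1[t0], c2[t0]); }

  IntegerMatrix merge_matrix() const {
    IntegerMatrix out(nrow, 2);
    for (int t = 0; t < nrow; ++t) { out(t, 0) = c1[t]; out(t, 1) = c2[t]; }
    return out;
  }
};

// sum_k |k - pi(k)|^p for the matching induced by the two leaf orders
static double pair_sum(const std::vector<int>& ol, const std::vector<int>& orr,
                       std::vector<int>& posr, double p) {
  int n = (int) ol.size();
  for (int k = 0; k < n; ++k) posr[orr[k] - 1] = k + 1;
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += dpow(std::abs((double) (k + 1) - posr[ol[k] - 1]), p);
  return s;
}

// worst displacement: V_r the exact reverse of V_l, i.e. pi(k) = n+1-k
static double worst_sum(int n, double p) {
  double s = 0.0;
  for (int k = 1; k <= n; ++k) s += dpow(std::abs(2.0 * k - n - 1.0), p);
  return s;
}

// inversions of a permutation by merge counting, O(n log n)
static long long merge_count(std::vector<int>& a, std::vector<int>& buf, int lo, int hi) {
  if (hi - lo <= 1) return 0;
  int mid = (lo + hi) / 2;
  long long inv = merge_count(a, buf, lo, mid) + merge_count(a, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (a[i] <= a[j]) buf[k++] = a[i++];
    else { inv += mid - i; buf[k++] = a[j++]; }
  }
  while (i < mid) buf[k++] = a[i++];
  while (j < hi) buf[k++] = a[j++];
  for (int t = lo; t < hi; ++t) a[t] = buf[t];
  return inv;
}

static long long count_crossings(const std::vector<int>& ol, const std::vector<int>& orr,
                                 std::vector<int>& posr) {
  int n = (int) ol.size();
  for (int k = 0; k < n; ++k) posr[orr[k] - 1] = k + 1;
  std::vector<int> pi(n), buf(n);
  for (int k = 0; k < n; ++k) pi[k] = posr[ol[k] - 1];
  return merge_count(pi, buf, 0, n);
}

struct Trace {
  int passes = 0;
  long long evals = 0;
  std::vector<int> side, row;
};

// Greedy alternating one-sided hill climb: scan i = 1..n-1 on the right tree
// accepting strictly improving swaps, then on the left, repeat until a full
// pass accepts nothing. `cur` and the Side orders are kept current.
static double run_step2side(Side& l, Side& r, double p, double tol, double worst,
                            Trace& tr, std::vector<int>& posr, double cur) {
  bool improved = true;
  while (improved) {
    improved = false;
    tr.passes++;
    for (int i = 0; i < r.nrow; ++i) {
      r.swap_row(i);
      r.compute_order();
      double cand = pair_sum(l.order, r.order, posr, p) / worst;
      tr.evals++;
      if (cand < cur - tol) {
        cur = cand;
        improved = true;
        tr.side.push_back(1);
        tr.row.push_back(i + 1);
      } else {
        r.swap_row(i);
        r.compute_order();
      }
    }
    for (int i = 0; i < l.nrow; ++i) {
      l.swap_row(i);
      l.compute_order();
      double cand = pair_sum(l.order, r.order, posr, p) / worst;
      tr.evals++;
      if (cand < cur - tol) {
        cur = cand;
        improved = true;
        tr.side.push_back(2);
        tr.row.push_back(i + 1);
      } else {
        l.swap_row(i);
        l.compute_order();
      }
    }
  }
  return cur;
}

// [[Rcpp::export]]
List cpp_metrics(IntegerMatrix ml, IntegerMatrix mr, int n, double p) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double s = pair_sum(l.order, r.order, posr, p);
  double w = worst_sum(n, p);
  double x = (double) count_crossings(l.order, r.order, posr);
  return List::create(_["power_sum"] = s, _["worst_sum"] = w, _["crossings"] = x);
}

// [[Rcpp::export]]
IntegerVector cpp_leaf_order(IntegerMatrix mg, int n) {
  Side s;
  s.init(mg, n);
  s.compute_order();
  return IntegerVector(s.order.begin(), s.order.end());
}

// [[Rcpp::export]]
List cpp_step2side(IntegerMatrix ml, IntegerMatrix mr, int n, double p, double tol) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double worst = worst_sum(n, p);
  double cur = pair_sum(l.order, r.order, posr, p) / worst;
  Trace tr;
  cur = run_step2side(l, r, p, tol, worst, tr, posr, cur);
  return List::create(
    _["left"] = l.merge_matrix(), _["right"] = r.merge_matrix(),
    _["entanglement"] = cur, _["passes"] = tr.passes,
    _["evaluations"] = (double) tr.evals,
    _["side"] = IntegerVector(tr.side.begin(), tr.side.end()),
    _["row"] = IntegerVector(tr.row.begin(), tr.row.end()));
}

// step2side to convergence, then a first-improvement scan over all
// simultaneous pairs (Omega_i left, Omega_j right); repeat until neither
// phase reduces the entanglement.
// [[Rcpp::export]]
List cpp_step_both_sides(IntegerMatrix ml, IntegerMatrix mr, int n, double p, double tol) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double worst = worst_sum(n, p);
  double cur = pair_sum(l.order, r.order, posr, p) / worst;
  Trace tr;
  int outer = 0;
  while (true) {
    outer++;
    size_t acc_before = tr.side.size();
    cur = run_step2side(l, r, p, tol, worst, tr, posr, cur);
    bool s2s_accepted = tr.side.size() > acc_before;
    bool pair_accepted = false;
    for (int i = 0; i < l.nrow; ++i) {
      for (int j = 0; j < r.nrow; ++j) {
        l.swap_row(i);
        r.swap_row(j);
        l.compute_order();
        r.compute_order();
        double cand = pair_sum(l.order, r.order, posr, p) / worst;
        tr.evals++;
        if (cand < cur - tol) {
          cur = cand;
          pair_accepted = true;
        } else {
          l.swap_row(i);
          r.swap_row(j);
          l.compute_order();
          r.compute_order();
        }
      }
    }
    if (!s2s_accepted && !pair_accepted) break;
  }
  return List::create(
    _["left"] = l.merge_matrix(), _["right"] = r.merge_matrix(),
    _["entanglement"] = cur, _["passes"] = tr.passes, _["outer"] = outer,
    _["evaluations"] = (double) tr.evals,
    _["side"] = IntegerVector(tr.side.begin(), tr.side.end()),
    _["row"] = IntegerVector(tr.row.begin(), tr.row.end()));
}

// Pick the best of the symmetric/asymmetric quad mu_ij(L) = {L, swap-left,
// swap-right, swap-both}; accept only if strictly better than `cur` by tol
// (ties go to the earliest candidate, so the incumbent wins exact ties).
// Returns the new entanglement; Sides are left holding the chosen layout.
static double quad_select(Side& l, Side& r, int ti, int tj, double p, double tol,
                          double worst, std::vector<int>& posr, double cur,
                          long long& evals, bool& accepted) {
  double bestv = cur - tol;
  int bestc = 0;
  for (int c = 1; c <= 3; ++c) {
    if (c & 1) l.swap_row(ti);
    if (c & 2) r.swap_row(tj);
    if (c & 1) l.compute_order();
    if (c & 2) r.compute_order();
    double cand = pair_sum(l.order, r.order, posr, p) / worst;
    evals++;
    if (cand < bestv) { bestv = cand; bestc = c; }
    if (c & 1) l.swap_row(ti);
    if (c & 2) r.swap_row(tj);
    if (c & 1) l.compute_order();
    if (c & 2) r.compute_order();
  }
  accepted = bestc != 0;
  if (accepted) {
    if (bestc & 1) { l.swap_row(ti); l.compute_order(); }
    if (bestc & 2) { r.swap_row(tj); r.compute_order(); }
    return bestv;
  }
  return cur;
}

// Symmetric optimization: L <- xi(mu_i(L)) for i = 1..n-m-1 (leaves toward
// the root), repeated until a full sweep yields no reduction.
static double run_sym_sweep(Side& l, Side& r, int m, double p, double tol, double worst,
                            std::vector<int>& posr, double cur, long long& evals) {
  int limit = l.nrow - m;  // number of sweep steps, n-m-1
  if (limit <= 0) return cur;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i0 = 0; i0 < limit; ++i0) {
      bool acc = false;
      cur = quad_select(l, r, i0, i0, p, tol, worst, posr, cur, evals, acc);
      if (acc) improved = true;
    }
  }
  return cur;
}

// Asymmetric optimization: for every leaf k, apply xi over the quad at rows
// (tau(k, Z_l), tau(k, Z_r)); repeat the full scan until a pass leaves the
// layout unchanged. tau is invariant under Omega, so locations are built once.
static double run_asym_pass(Side& l, Side& r, double p, double tol, double worst,
                            std::vector<int>& posr, double cur, long long& evals) {
  int n = l.n;
  std::vector<int> locl(2 * n, -1), locr(2 * n, -1);
  for (int t = 0; t < l.nrow; ++t) { locl[l.c1[t] - 1] = t; locl[l.c2[t] - 1] = t; }
  for (int t = 0; t < r.nrow; ++t) { locr[r.c1[t] - 1] = t; locr[r.c2[t] - 1] = t; }
  bool changed = true;
  while (changed) {
    changed = false;
    for (int k = 0; k < n; ++k) {
      bool acc = false;
      cur = quad_select(l, r, locl[k], locr[k], p, tol, worst, posr, cur, evals, acc);
      if (acc) changed = true;
    }
  }
  return cur;
}

// [[Rcpp::export]]
List cpp_symmetric_sweep(IntegerMatrix ml, IntegerMatrix mr, int n, int m,
                         double p, double tol) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double worst = worst_sum(n, p);
  double cur = pair_sum(l.order, r.order, posr, p) / worst;
  long long evals = 0;
  cur = run_sym_sweep(l, r, m, p, tol, worst, posr, cur, evals);
  return List::create(_["left"] = l.merge_matrix(), _["right"] = r.merge_matrix(),
                      _["entanglement"] = cur, _["evaluations"] = (double) evals);
}

// [[Rcpp::export]]
List cpp_asymmetric_pass(IntegerMatrix ml, IntegerMatrix mr, int n, double p, double tol) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double worst = worst_sum(n, p);
  double cur = pair_sum(l.order, r.order, posr, p) / worst;
  long long evals = 0;
  cur = run_asym_pass(l, r, p, tol, worst, posr, cur, evals);
  return List::create(_["left"] = l.merge_matrix(), _["right"] = r.merge_matrix(),
                      _["entanglement"] = cur, _["evaluations"] = (double) evals);
}

// The per-candidate optimizer of the shuffle-and-untangle scheme: symmetric
// sweep at depth m followed by the asymmetric pass.
// [[Rcpp::export]]
List cpp_shuntan_optimize(IntegerMatrix ml, IntegerMatrix mr, int n, int m,
                          double p, double tol) {
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  l.compute_order();
  r.compute_order();
  std::vector<int> posr(n);
  double worst = worst_sum(n, p);
  double cur = pair_sum(l.order, r.order, posr, p) / worst;
  long long evals = 0;
  cur = run_sym_sweep(l, r, m, p, tol, worst, posr, cur, evals);
  cur = run_asym_pass(l, r, p, tol, worst, posr, cur, evals);
  return List::create(_["left"] = l.merge_matrix(), _["right"] = r.merge_matrix(),
                      _["entanglement"] = cur, _["evaluations"] = (double) evals);
}

// Exhaustive enumeration of all 2^(n-1) x 2^(n-1) swap configurations.
// Returns the first (in lexicographic mask order, left mask outer) layout
// attaining the minimum entanglement, and the minimum crossing count over
// all layouts (which may occur at a different configuration).
// [[Rcpp::export]]
List cpp_oracle(IntegerMatrix ml, IntegerMatrix mr, int n, double p) {
  int nr = n - 1;
  int64_t nconf = (int64_t) 1 << nr;
  Side l, r;
  l.init(ml, n);
  r.init(mr, n);
  std::vector<int> ordl((size_t) nconf * n), posr_all((size_t) nconf * n);
  for (int64_t mask = 0; mask < nconf; ++mask) {
    for (int t = 0; t < nr; ++t) if (mask & ((int64_t) 1 << t)) l.swap_row(t);
    l.compute_order();
    for (int k = 0; k < n; ++k) ordl[(size_t) mask * n + k] = l.order[k];
    for (int t = 0; t < nr; ++t) if (mask & ((int64_t) 1 << t)) l.swap_row(t);
  }
  for (int64_t mask = 0; mask < nconf; ++mask) {
    for (int t = 0; t < nr; ++t) if (mask & ((int64_t) 1 << t)) r.swap_row(t);
    r.compute_order();
    for (int k = 0; k < n; ++k) posr_all[(size_t) mask * n + (r.order[k] - 1)] = k + 1;
    for (int t = 0; t < nr; ++t) if (mask & ((int64_t) 1 << t)) r.swap_row(t);
  }
  double worst = worst_sum(n, p);
  double best = R_PosInf;
  int64_t bl = 0, br = 0;
  long long minx = LLONG_MAX;
  std::vector<int> pi(n);
  for (int64_t a = 0; a < nconf; ++a) {
    const int* ol = &ordl[(size_t) a * n];
    for (int64_t b = 0; b < nconf; ++b) {
      const int* pr = &posr_all[(size_t) b * n];
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        pi[k] = pr[ol[k] - 1];
        s += dpow(std::abs((double) (k + 1) - pi[k]), p);
      }
      if (s < best) { best = s; bl = a; br = b; }
      long long inv = 0;  // O(n^2) is fine at oracle sizes
      for (int u = 0; u < n; ++u)
        for (int v = u + 1; v < n; ++v)
          if (pi[u] > pi[v]) inv++;
      if (inv < minx) minx = inv;
    }
  }
  return List::create(
    _["min_entanglement"] = best / worst,
    _["min_crossings"] = (double) minx,
    _["mask_left"] = (double) bl, _["mask_right"] = (double) br,
    _["layouts_evaluated"] = (double) nconf * (double) nconf);
}
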