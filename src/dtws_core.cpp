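#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Balanced, end-unanchored warping of a query series y (length N) onto a
// reference series x (length M >= N).  Exactly M - N reference columns are
// omitted, every query point is aligned to at least one selected column, and
// multiple mapping is allowed in both directions (one query point to several
// consecutive columns, and -- when many_to_one is true -- several query
// points to one column).
//
// State (i, j, k, s): minimal cost of aligning the first i query points to
// the first j reference columns with k omissions so far; s == 1 iff column j
// is currently matched, so that it may be extended to a further query point.
// The s bit prevents an omitted column from being reused by a many-to-one
// extension.  Keys are minimised lexicographically: (cost, number of pairs).
//
// Transitions into (i, j, k, s):
//   a: omit column j        from (i,   j-1, k-1, *)  -> s = 0, cost += 0
//   b: new match (i, j)     from (i-1, j-1, k,   *)  -> s = 1, cost += d(i,j)
//   c: extend query point i from (i,   j-1, k,   *)  -> s = 1, cost += d(i,j)
//   d: extend column j      from (i-1, j,   k,   1)  -> s = 1, cost += d(i,j)
// with d(i, j) = (x_j - y_i)^2.  Omissions are free apart from the k budget,
// so leading and trailing columns can be dropped (end-unanchored reference).

// [[Rcpp::export(name = ".dtws_core")]]
List dtws_core(NumericVector x, NumericVector y, bool many_to_one) {
  const int M = x.size(), N = y.size(), K = M - N;
  if (N < 2) stop("query series must have at least 2 points");
  if (K < 0) stop("reference must be at least as long as the query");
  for (int j = 0; j < M; ++j)
    if (!R_finite(x[j])) stop("non-finite expression value in reference");
  for (int i = 0; i < N; ++i)
    if (!R_finite(y[i])) stop("non-finite expression value in query");

  const double INF = R_PosInf;
  const R_xlen_t SZ = (R_xlen_t)(N + 1) * (M + 1) * (K + 1) * 2;
  std::vector<double> cost(SZ, INF);
  std::vector<int> npair(SZ, INT_MAX);
  std::vector<signed char> move(SZ, -1);  // move*2 + predecessor s

  // 1-based i, j in the maths; arrays are 0..N, 0..M, 0..K, 0..1
  const R_xlen_t strideJ = (R_xlen_t)(K + 1) * 2;
  const R_xlen_t strideI = (R_xlen_t)(M + 1) * strideJ;
#define IDX(i, j, k, s) ((R_xlen_t)(i) * strideI + (R_xlen_t)(j) * strideJ + \
                         (R_xlen_t)(k) * 2 + (s))

  cost[IDX(0, 0, 0, 0)] = 0.0;
  npair[IDX(0, 0, 0, 0)] = 0;

  for (int i = 0; i <= N; ++i) {
    for (int j = 0; j <= M; ++j) {
      const int kmax = j < K ? j : K;
      const double d = (i >= 1 && j >= 1)
                           ? (x[j - 1] - y[i - 1]) * (x[j - 1] - y[i - 1])
                           : 0.0;
      for (int k = 0; k <= kmax; ++k) {
        for (int s = 0; s <= 1; ++s) {
          if (i == 0 && j == 0) continue;  // base cell
          double best = INF;
          int bestnp = INT_MAX;
          signed char bestmv = -1;
          // candidate predecessors, fixed evaluation order for determinism
          if (s == 0) {
            if (j >= 1 && k >= 1) {  // (a) omit column j
              for (int ps = 0; ps <= 1; ++ps) {
                const R_xlen_t p = IDX(i, j - 1, k - 1, ps);
                if (cost[p] < best ||
                    (cost[p] == best && npair[p] < bestnp)) {
                  best = cost[p]; bestnp = npair[p];
                  bestmv = (signed char)(0 * 2 + ps);
                }
              }
            }
          } else {
            if (i >= 1 && j >= 1) {
              for (int ps = 0; ps <= 1; ++ps) {  // (b) new match
                const R_xlen_t p = IDX(i - 1, j - 1, k, ps);
                if (cost[p] == INF) continue;
                const double c = cost[p] + d; const int n2 = npair[p] + 1;
                if (c < best || (c == best && n2 < bestnp)) {
                  best = c; bestnp = n2; bestmv = (signed char)(1 * 2 + ps);
                }
              }
              if (many_to_one) {  // (d) extend column j down the query
                const R_xlen_t p = IDX(i - 1, j, k, 1);
                if (cost[p] != INF) {
                  const double c = cost[p] + d; const int n2 = npair[p] + 1;
                  if (c < best || (c == best && n2 < bestnp)) {
                    best = c; bestnp = n2; bestmv = (signed char)(3 * 2 + 1);
                  }
                }
              }
              for (int ps = 0; ps <= 1; ++ps) {  // (c) extend query point i
                const R_xlen_t p = IDX(i, j - 1, k, ps);
                if (cost[p] == INF) continue;
                const double c = cost[p] + d; const int n2 = npair[p] + 1;
                if (c < best || (c == best && n2 < bestnp)) {
                  best = c; bestnp = n2; bestmv = (signed char)(2 * 2 + ps);
                }
              }
            }
          }
          const R_xlen_t q = IDX(i, j, k, s);
          cost[q] = best; npair[q] = bestnp; move[q] = bestmv;
        }
      }
    }
  }

  // terminal: all query points aligned, all columns consumed, K omissions
  int sT = 0;
  {
    const R_xlen_t t0 = IDX(N, M, K, 0), t1 = IDX(N, M, K, 1);
    if (cost[t1] < cost[t0] ||
        (cost[t1] == cost[t0] && npair[t1] < npair[t0]))
      sT = 1;
  }
  const R_xlen_t term = IDX(N, M, K, sT);
  if (cost[term] == INF) stop("no feasible balanced alignment");  // cannot happen

  // traceback
  std::vector<int> pi, pj, om;
  int i = N, j = M, k = K, s = sT;
  while (!(i == 0 && j == 0 && k == 0 && s == 0)) {
    const signed char code = move[IDX(i, j, k, s)];
    if (code < 0) stop("internal error: broken traceback");
    const int m = code >> 1, ps = code & 1;
    if (m == 0) { om.push_back(j); --j; --k; }
    else if (m == 1) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (m == 2) { pi.push_back(i); pj.push_back(j); --j; }
    else { pi.push_back(i); pj.push_back(j); --i; }
    s = ps;
  }

  const int P = (int)pi.size();
  IntegerMatrix pairs(P, 2);
  for (int r = 0; r < P; ++r) {  // reverse into ascending order
    pairs(r, 0) = pi[P - 1 - r];
    pairs(r, 1) = pj[P - 1 - r];
  }
  IntegerVector omitted(om.size());
  for (int r = 0; r < (int)om.size(); ++r)
    omitted[r] = om[om.size() - 1 - r];

  return List::create(
      _["cost"] = cost[term], _["pairs"] = pairs, _["omitted"] = omitted,
      _["n_pairs"] = npair[term],
      _["cells"] = (double)(N + 1) * (M + 1) * (K + 1));
#undef IDX
}
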