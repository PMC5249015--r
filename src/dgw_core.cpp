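#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Local distance between bin i of a and bin j of b.
// Matrices are column-major with n_bins rows and n_tracks columns.
// metric: 0 = squared Euclidean, 1 = cosine (1 - dot/(|x||y|)),
// with the conventions d(x, 0) = 1 for x != 0 and d(0, 0) = 0.
static inline double bin_dist(const double* a, int N, const double* b, int M,
                              int i, int j, int T, int metric) {
  if (metric == 0) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      double diff = a[i + (std::size_t)t * N] - b[j + (std::size_t)t * M];
      s += diff * diff;
    }
    return s;
  }
  double dot = 0.0, na = 0.0, nb = 0.0;
  for (int t = 0; t < T; ++t) {
    double x = a[i + (std::size_t)t * N], y = b[j + (std::size_t)t * M];
    dot += x * y; na += x * x; nb += y * y;
  }
  if (na == 0.0 && nb == 0.0) return 0.0;
  if (na == 0.0 || nb == 0.0) return 1.0;
  double d = 1.0 - dot / std::sqrt(na * nb);
  return d < 0.0 ? 0.0 : d;
}

// Column window [lo, hi] of the slanted Sakoe-Chiba band at row i.
// The band is centred on j = i*(M-1)/(N-1) with effective half-width
// max(k, |N-M|+1) so the corridor is always feasible; k <= 0 disables it.
static inline void band_window(int i, int N, int M, int k, int& lo, int& hi) {
  if (k <= 0) { lo = 0; hi = M - 1; return; }
  int w = std::max(k, std::abs(N - M) + 1);
  double c = (N > 1) ? (double)i * (M - 1) / (N - 1) : 0.0;
  lo = std::max(0, (int)std::floor(c) - w);
  hi = std::min(M - 1, (int)std::ceil(c) + w);
}

// Core DP. Steps (1,1), (1,0), (0,1) with unit weights; the accumulated
// cost is the plain sum of local distances along the path (no
// normalisation).  gamma > 1 applies a multiplicative penalty
// gamma^(run length) to the local cost of repeated non-diagonal steps in
// the same direction, discouraging long compressions; gamma = 1 is the
// plain recursion.  Backtrack ties prefer the diagonal step, then the step
// advancing the longer sequence.
//
// Returns the distance; if `path` is non-null, fills it with 1-based
// (i, j) pairs from (1,1) to (N,M).  If `acc_out` is non-null it receives
// the accumulated-cost matrix (INF outside the band).
static double dtw_dp(const double* a, int N, const double* b, int M, int T,
                     int metric, int band, double gamma,
                     std::vector<std::pair<int,int> >* path,
                     std::vector<double>* acc_out) {
  const std::size_t sz = (std::size_t)N * M;
  if (gamma <= 1.0) {
    std::vector<double> D(sz, INF);
    for (int i = 0; i < N; ++i) {
      int lo, hi; band_window(i, N, M, band, lo, hi);
      for (int j = lo; j <= hi; ++j) {
        double d = bin_dist(a, N, b, M, i, j, T, metric);
        double best;
        if (i == 0 && j == 0) best = 0.0;
        else {
          best = INF;
          if (i > 0 && j > 0) best = D[(std::size_t)(i - 1) * M + (j - 1)];
          if (i > 0) best = std::min(best, D[(std::size_t)(i - 1) * M + j]);
          if (j > 0) best = std::min(best, D[(std::size_t)i * M + (j - 1)]);
        }
        D[(std::size_t)i * M + j] = d + best;
      }
    }
    double dist = D[sz - 1];
    if (acc_out) *acc_out = D;
    if (path) {
      path->clear();
      int i = N - 1, j = M - 1;
      path->push_back(std::make_pair(i + 1, j + 1));
      bool a_longer = (N >= M);
      while (i > 0 || j > 0) {
        double dg = (i > 0 && j > 0) ? D[(std::size_t)(i - 1) * M + (j - 1)] : INF;
        double up = (i > 0) ? D[(std::size_t)(i - 1) * M + j] : INF;
        double lf = (j > 0) ? D[(std::size_t)i * M + (j - 1)] : INF;
        double m = std::min(dg, std::min(up, lf));
        if (dg == m) { --i; --j; }
        else if (a_longer ? (up == m) : (lf == m)) { if (a_longer) --i; else --j; }
        else { if (a_longer) --j; else --i; }
        path->push_back(std::make_pair(i + 1, j + 1));
      }
      std::reverse(path->begin(), path->end());
    }
    return dist;
  }

  // gamma > 1: per-cell state over the incoming step direction
  // (0 = diagonal, 1 = advance a, 2 = advance b) with the run length of
  // consecutive same-direction non-diagonal steps that achieved the best
  // cost for that state (ties towards shorter runs).
  std::vector<double> C(sz * 3, INF);
  std::vector<int> run(sz * 3, 0);
  std::vector<signed char> from(sz * 3, -1);
  for (int i = 0; i < N; ++i) {
    int lo, hi; band_window(i, N, M, band, lo, hi);
    for (int j = lo; j <= hi; ++j) {
      std::size_t cell = ((std::size_t)i * M + j) * 3;
      double d = bin_dist(a, N, b, M, i, j, T, metric);
      if (i == 0 && j == 0) { C[cell] = d; run[cell] = 0; continue; }
      for (int dir = 0; dir < 3; ++dir) {
        int pi = i - (dir != 2 ? 1 : 0), pj = j - (dir != 1 ? 1 : 0);
        if (pi < 0 || pj < 0) continue;
        std::size_t pc = ((std::size_t)pi * M + pj) * 3;
        for (int pd = 0; pd < 3; ++pd) {
          if (C[pc + pd] == INF) continue;
          int r = (dir == 0) ? 0 : ((pd == dir) ? run[pc + pd] + 1 : 1);
          double step = (dir == 0) ? d : d * std::pow(gamma, r);
          double cand = C[pc + pd] + step;
          std::size_t s = cell + dir;
          if (cand < C[s] || (cand == C[s] && r < run[s])) {
            C[s] = cand; run[s] = r; from[s] = (signed char)pd;
          }
        }
      }
    }
  }
  std::size_t last = (sz - 1) * 3;
  int bd = 0;
  for (int dir = 1; dir < 3; ++dir) if (C[last + dir] < C[last + bd]) bd = dir;
  double dist = C[last + bd];
  if (acc_out) {
    acc_out->assign(sz, INF);
    for (std::size_t c = 0; c < sz; ++c)
      (*acc_out)[c] = std::min(C[c * 3], std::min(C[c * 3 + 1], C[c * 3 + 2]));
  }
  if (path) {
    path->clear();
    int i = N - 1, j = M - 1, dir = bd;
    while (true) {
      path->push_back(std::make_pair(i + 1, j + 1));
      if (i == 0 && j == 0) break;
      int pd = from[((std::size_t)i * M + j) * 3 + dir];
      if (dir != 2) --i;
      if (dir != 1) --j;
      dir = pd;
    }
    std::reverse(path->begin(), path->end());
  }
  return dist;
}

// [[Rcpp::export(name = ".cpp_dtw")]]
List cpp_dtw(NumericMatrix a, NumericMatrix b, int metric, int band,
             double gamma, bool want_path, bool want_matrix) {
  int N = a.nrow(), M = b.nrow(), T = a.ncol();
  if (b.ncol() != T) stop("track count mismatch: %d vs %d", T, b.ncol());
  if (N < 1 || M < 1) stop("empty profile");
  std::vector<std::pair<int,int> > path;
  std::vector<double> acc;
  double dist = dtw_dp(REAL(a), N, REAL(b), M, T, metric, band, gamma,
                       want_path ? &path : (std::vector<std::pair<int,int> >*)0,
                       want_matrix ? &acc : (std::vector<double>*)0);
  List out = List::create(Named("distance") = dist);
  if (want_path) {
    IntegerMatrix P(path.size(), 2);
    for (std::size_t k = 0; k < path.size(); ++k) {
      P(k, 0) = path[k].first; P(k, 1) = path[k].second;
    }
    out["path"] = P;
  }
  if (want_matrix) {
    NumericMatrix A(N, M);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < M; ++j)
        A(i, j) = acc[(std::size_t)i * M + j];
    out["cost_matrix"] = A;
  }
  return out;
}

// All n*(n-1)/2 flip-aware distances over a list of profile matrices, in
// the condensed order used by stats::dist (pair (i, j), i < j, row-major).
// flipped[k] records whether the reversed orientation of the second
// profile of the pair won strictly (ties keep the annotated orientation).
// `rows` (1-based first indices i; empty = all) restricts the computation
// to the pairs whose first index is in `rows`, for parallel chunking;
// the entries returned are those rows' condensed segments, in row order.
// [[Rcpp::export(name = ".cpp_pairwise_flip")]]
List cpp_pairwise_flip(List mats, int metric, int band, double gamma,
                       bool flip_aware, IntegerVector rows) {
  int n = mats.size();
  std::vector<NumericMatrix> fwd(n);
  std::vector<NumericMatrix> rev(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = mats[i];
    fwd[i] = m;
    if (flip_aware) {
      NumericMatrix r(m.nrow(), m.ncol());
      for (int t = 0; t < m.ncol(); ++t)
        for (int k = 0; k < m.nrow(); ++k)
          r(m.nrow() - 1 - k, t) = m(k, t);
      rev[i] = r;
    }
  }
  std::vector<int> row_idx;
  if (rows.size() == 0) {
    for (int i = 0; i < n - 1; ++i) row_idx.push_back(i);
  } else {
    for (int k = 0; k < rows.size(); ++k) row_idx.push_back(rows[k] - 1);
  }
  std::size_t np = 0;
  for (std::size_t k = 0; k < row_idx.size(); ++k) np += n - 1 - row_idx[k];
  NumericVector dist(np);
  LogicalVector flip(np);
  std::size_t idx = 0;
  for (std::size_t k = 0; k < row_idx.size(); ++k) {
    int i = row_idx[k];
    for (int j = i + 1; j < n; ++j, ++idx) {
      NumericMatrix& A = fwd[i];
      double d0 = dtw_dp(REAL(A), A.nrow(), REAL(fwd[j]), fwd[j].nrow(),
                         A.ncol(), metric, band, gamma, 0, 0);
      bool fl = false;
      double d = d0;
      if (flip_aware) {
        double d1 = dtw_dp(REAL(A), A.nrow(), REAL(rev[j]), rev[j].nrow(),
                           A.ncol(), metric, band, gamma, 0, 0);
        if (d1 < d0) { d = d1; fl = true; }
      }
      dist[idx] = d; flip[idx] = fl;
    }
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("distance") = dist, Named("flipped") = flip);
}

// Minimum-cost assignment (Hungarian algorithm, O(n^3) shortest
// augmenting path with potentials) on a square cost matrix.
// Returns the 1-based column assigned to each row.
// [[Rcpp::export(name = ".cpp_hungarian")]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
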