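#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Constrained DTW dynamic programme.
//
// States per cell: 0 = arrived diagonally, 1/2 = arrived by 1 or 2
// consecutive vertical steps (a advances), 3/4 = same for horizontal steps
// (b advances).  A third consecutive step in the same off-diagonal direction
// is forbidden, so one sample of either series aligns to at most three of
// the other.  Off-diagonal steps pay an additive penalty that decays
// linearly with path progress from `start_penalty` to `end_penalty`.
// `admissible` is the parallelogram band mask (n x m, column-major).
//
// Returns total (unnormalised) optimal cost, the optimal path, and a
// feasibility flag; normalisation is done by the R wrapper.
//
// [[Rcpp::export(name = ".dtw_core_cpp")]]
List dtw_core_cpp(const NumericVector& a,
                  const NumericVector& b,
                  const LogicalMatrix& admissible,
                  const double start_penalty,
                  const double end_penalty) {
  const int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("series must be non-empty");
  if (admissible.nrow() != n || admissible.ncol() != m)
    stop("band mask has wrong dimensions");

  const double inf = std::numeric_limits<double>::infinity();
  const int S = 5;
  // cost[(i*m + j)*S + s]
  std::vector<double> cost((size_t)n * m * S, inf);
  std::vector<signed char> prev((size_t)n * m * S, -1);

  // progress in [0,1] used for the penalty schedule
  auto progress = [&](int i, int j) -> double {
    double pi = (n > 1) ? (double)i / (n - 1) : 1.0;
    double pj = (m > 1) ? (double)j / (m - 1) : 1.0;
    return 0.5 * (pi + pj);
  };
  auto penalty = [&](int i, int j) -> double {
    double p = progress(i, j);
    return start_penalty + (end_penalty - start_penalty) * p;
  };
  auto idx = [&](int i, int j, int s) -> size_t {
    return ((size_t)i * m + j) * S + s;
  };

  if (admissible(0, 0))
    cost[idx(0, 0, 0)] = std::fabs(a[0] - b[0]);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      if (!admissible(i, j)) continue;
      const double local = std::fabs(a[i] - b[j]);
      const double pen = penalty(i, j);
      // diagonal arrival: from (i-1, j-1) any state
      if (i > 0 && j > 0) {
        for (int s = 0; s < S; ++s) {
          double c = cost[idx(i - 1, j - 1, s)];
          if (c + local < cost[idx(i, j, 0)]) {
            cost[idx(i, j, 0)] = c + local;
            prev[idx(i, j, 0)] = (signed char)s;
          }
        }
      }
      // vertical arrival (a advances, b repeats): run resets on direction change
      if (i > 0) {
        // into run-1: from diagonal or horizontal states
        const int from1[3] = {0, 3, 4};
        for (int k = 0; k < 3; ++k) {
          double c = cost[idx(i - 1, j, from1[k])];
          if (c + local + pen < cost[idx(i, j, 1)]) {
            cost[idx(i, j, 1)] = c + local + pen;
            prev[idx(i, j, 1)] = (signed char)from1[k];
          }
        }
        // into run-2: only from vertical run-1
        double c = cost[idx(i - 1, j, 1)];
        if (c + local + pen < cost[idx(i, j, 2)]) {
          cost[idx(i, j, 2)] = c + local + pen;
          prev[idx(i, j, 2)] = 1;
        }
      }
      // horizontal arrival (b advances, a repeats)
      if (j > 0) {
        const int from1[3] = {0, 1, 2};
        for (int k = 0; k < 3; ++k) {
          double c = cost[idx(i, j - 1, from1[k])];
          if (c + local + pen < cost[idx(i, j, 3)]) {
            cost[idx(i, j, 3)] = c + local + pen;
            prev[idx(i, j, 3)] = (signed char)from1[k];
          }
        }
        double c = cost[idx(i, j - 1, 3)];
        if (c + local + pen < cost[idx(i, j, 4)]) {
          cost[idx(i, j, 4)] = c + local + pen;
          prev[idx(i, j, 4)] = 3;
        }
      }
    }
  }

  // best terminal state at (n-1, m-1)
  int best_s = -1;
  double best = inf;
  for (int s = 0; s < S; ++s) {
    double c = cost[idx(n - 1, m - 1, s)];
    if (c < best) { best = c; best_s = s; }
  }
  if (best_s < 0) {
    return List::create(_["feasible"] = false,
                        _["total_cost"] = NA_REAL,
                        _["path"] = R_NilValue);
  }

  // backtrack
  std::vector<int> pi_, pj_;
  int i = n - 1, j = m - 1, s = best_s;
  while (true) {
    pi_.push_back(i + 1); // 1-based for R
    pj_.push_back(j + 1);
    if (i == 0 && j == 0) break;
    int ps = prev[idx(i, j, s)];
    if (s == 0) { --i; --j; }
    else if (s == 1 || s == 2) { --i; }
    else { --j; }
    s = ps;
  }
  const int L = pi_.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi_[L - 1 - k];
    path(k, 1) = pj_[L - 1 - k];
  }
  colnames(path) = CharacterVector::create("i", "j");

  return List::create(_["feasible"] = true,
                      _["total_cost"] = best,
                      _["path"] = path);
}
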