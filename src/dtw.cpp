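#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Series are stored channels x frames, so one frame is one (contiguous) column.

static inline double frame_cost(const double *x, const double *y, int C,
                                int cost_type) {
  double acc = 0.0;
  if (cost_type == 1) { // manhattan: per-channel absolute-difference sum
    for (int c = 0; c < C; ++c) acc += std::fabs(x[c] - y[c]);
    return acc;
  }
  for (int c = 0; c < C; ++c) {
    double d = x[c] - y[c];
    acc += d * d;
  }
  // 0: euclidean; 2: squared euclidean (the barycenter-averaging metric)
  return cost_type == 0 ? std::sqrt(acc) : acc;
}

// Accumulated-cost DP over the step set {(1,0),(0,1),(1,1)}, endpoints fixed
// at (1,1) and (N,M). Returns the full matrix so callers can backtrack.
static std::vector<double> accumulate(const NumericMatrix &X,
                                      const NumericMatrix &Y, int cost_type) {
  const int C = X.nrow();
  const int N = X.ncol(), M = Y.ncol();
  std::vector<double> D((size_t)N * M);
  const double *xp = REAL(X), *yp = REAL(Y);
  for (int i = 0; i < N; ++i) {
    const double *xi = xp + (size_t)i * C;
    double *Di = &D[(size_t)i * M];
    for (int j = 0; j < M; ++j) {
      double c = frame_cost(xi, yp + (size_t)j * C, C, cost_type);
      if (i == 0 && j == 0) {
        Di[j] = c;
      } else if (i == 0) {
        Di[j] = Di[j - 1] + c;
      } else if (j == 0) {
        Di[j] = D[(size_t)(i - 1) * M] + c;
      } else {
        const double *Dprev = &D[(size_t)(i - 1) * M];
        double best = Dprev[j - 1]; // diagonal
        if (Dprev[j] < best) best = Dprev[j];
        if (Di[j - 1] < best) best = Di[j - 1];
        Di[j] = best + c;
      }
    }
  }
  return D;
}

// [[Rcpp::export]]
double cpp_dtw_cost(NumericMatrix X, NumericMatrix Y, int cost_type) {
  std::vector<double> D = accumulate(X, Y, cost_type);
  return D[(size_t)X.ncol() * Y.ncol() - 1];
}

// Backtracked optimal path, deterministic tie rule: prefer the diagonal
// predecessor (1,1), then (1,0), then (0,1). 1-based index pairs.
// [[Rcpp::export]]
List cpp_dtw_path(NumericMatrix X, NumericMatrix Y, int cost_type) {
  const int N = X.ncol(), M = Y.ncol();
  std::vector<double> D = accumulate(X, Y, cost_type);
  std::vector<int> ni, mi;
  int i = N - 1, j = M - 1;
  ni.push_back(i + 1);
  mi.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double diag = D[(size_t)(i - 1) * M + (j - 1)];
      double up = D[(size_t)(i - 1) * M + j];
      double left = D[(size_t)i * M + (j - 1)];
      if (diag <= up && diag <= left) {
        --i;
        --j;
      } else if (up <= left) {
        --i;
      } else {
        --j;
      }
    }
    ni.push_back(i + 1);
    mi.push_back(j + 1);
  }
  const int L = (int)ni.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = ni[L - 1 - k];
    path(k, 1) = mi[L - 1 - k];
  }
  return List::create(_["raw_cost"] = D[(size_t)N * M - 1], _["path"] = path);
}

// Cross distance matrix between two lists of series; normalized divides each
// raw cost by sqrt(N^2 + M^2) (the cost-matrix diagonal).
// [[Rcpp::export]]
NumericMatrix cpp_dtw_cross(List A, List B, int cost_type, bool normalized) {
  const int nA = A.size(), nB = B.size();
  NumericMatrix out(nA, nB);
  for (int a = 0; a < nA; ++a) {
    NumericMatrix X = A[a];
    for (int b = 0; b < nB; ++b) {
      NumericMatrix Y = B[b];
      double d = cpp_dtw_cost(X, Y, cost_type);
      if (normalized) {
        double N = X.ncol(), M = Y.ncol();
        d /= std::sqrt(N * N + M * M);
      }
      out(a, b) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Symmetric pairwise matrix within one list (diagonal zero).
// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(List A, int cost_type, bool normalized) {
  const int n = A.size();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    NumericMatrix X = A[a];
    for (int b = a + 1; b < n; ++b) {
      NumericMatrix Y = A[b];
      double d = cpp_dtw_cost(X, Y, cost_type);
      if (normalized) {
        double N = X.ncol(), M = Y.ncol();
        d /= std::sqrt(N * N + M * M);
      }
      out(a, b) = d;
      out(b, a) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
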