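// Exact dynamic time warping under Euclidean local cost with steps
// {(1,0),(0,1),(1,1)}: a quadratic-memory oracle with backtrace, and a
// linear-memory divide-and-conquer variant that returns an identical cost
// (paths may differ only among equal-cost ties). Sequences are matrices with
// one row per time step.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline double dist_rows(const NumericMatrix& A, int i,
                               const NumericMatrix& B, int j) {
  double s = 0.0;
  const int d = A.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = A(i, k) - B(j, k);
    s += diff * diff;
  }
  return std::sqrt(s);
}

// contiguous row-major copy for the hot divide-and-conquer loops
struct SeqBuf {
  std::vector<double> v;
  int n, d;
  explicit SeqBuf(const NumericMatrix& M) : v((size_t)M.nrow() * M.ncol()),
                                            n(M.nrow()), d(M.ncol()) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < d; ++k) v[(size_t)i * d + k] = M(i, k);
  }
  inline const double* row(int i) const { return &v[(size_t)i * d]; }
};

static inline double dist_buf(const SeqBuf& A, int i, const SeqBuf& B,
                              int j) {
  const double* a = A.row(i);
  const double* b = B.row(j);
  double s = 0.0;
  for (int k = 0; k < A.d; ++k) {
    const double diff = a[k] - b[k];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// workspace instrumentation: doubles allocated by the current call
static R_xlen_t g_workspace_cells = 0;

// [[Rcpp::export(name = ".dtw_full_cpp")]]
List dtw_full_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("dtw: empty sequence");
  if (a.ncol() != b.ncol()) stop("dtw: feature dimensions differ");
  std::vector<double> D((size_t)n * m);
  std::vector<uint8_t> bt((size_t)n * m); // 0 diag, 1 up (1,0), 2 left (0,1)
  g_workspace_cells = (R_xlen_t)n * m;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double d = dist_rows(a, i, b, j);
      const size_t idx = (size_t)i * m + j;
      if (i == 0 && j == 0) { D[idx] = d; bt[idx] = 0; continue; }
      double best = R_PosInf; uint8_t step = 0;
      if (i > 0 && j > 0) { best = D[idx - m - 1]; step = 0; }
      if (i > 0 && D[idx - m] < best) { best = D[idx - m]; step = 1; }
      if (j > 0 && D[idx - 1] < best) { best = D[idx - 1]; step = 2; }
      D[idx] = d + best;
      bt[idx] = step;
    }
  }
  // backtrace
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i); pj.push_back(j);
    if (i == 0 && j == 0) break;
    const uint8_t s = bt[(size_t)i * m + j];
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k] + 1;   // 1-based for R
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return List::create(_["cost"] = D[(size_t)n * m - 1], _["path"] = path,
                      _["workspace_cells"] = (double)g_workspace_cells);
}

// forward costs over rows i0..i1 (cols j0..j1), path forced to start at
// (i0,j0); returns the cost row for row i1 into `out` (length j1-j0+1)
static void fwd_row(const SeqBuf& a, const SeqBuf& b,
                    int i0, int i1, int j0, int j1, std::vector<double>& out) {
  const int m = j1 - j0 + 1;
  std::vector<double> prev(m), cur(m);
  g_workspace_cells = std::max(g_workspace_cells, (R_xlen_t)(2 * m));
  for (int i = i0; i <= i1; ++i) {
    for (int j = 0; j < m; ++j) {
      const double d = dist_buf(a, i, b, j0 + j);
      if (i == i0 && j == 0) { cur[j] = d; continue; }
      double best = R_PosInf;
      if (i > i0 && j > 0) best = std::min(best, prev[j - 1]);
      if (i > i0) best = std::min(best, prev[j]);
      if (j > 0) best = std::min(best, cur[j - 1]);
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  out = prev;
}

// backward costs: cost of the path from (i,j) to (i1,j1) inclusive, for row
// i0 of the block
static void bwd_row(const SeqBuf& a, const SeqBuf& b,
                    int i0, int i1, int j0, int j1, std::vector<double>& out) {
  const int m = j1 - j0 + 1;
  std::vector<double> nxt(m), cur(m);
  g_workspace_cells = std::max(g_workspace_cells, (R_xlen_t)(2 * m));
  for (int i = i1; i >= i0; --i) {
    for (int j = m - 1; j >= 0; --j) {
      const double d = dist_buf(a, i, b, j0 + j);
      if (i == i1 && j == m - 1) { cur[j] = d; continue; }
      double best = R_PosInf;
      if (i < i1 && j < m - 1) best = std::min(best, nxt[j + 1]);
      if (i < i1) best = std::min(best, nxt[j]);
      if (j < m - 1) best = std::min(best, cur[j + 1]);
      cur[j] = d + best;
    }
    std::swap(nxt, cur);
  }
  out = nxt;
}

// small blocks: full DP restricted to the block, appending the path
// (excluding the starting cell when `skip_first`)
static void solve_block(const SeqBuf& a, const SeqBuf& b,
                        int i0, int i1, int j0, int j1, bool skip_first,
                        std::vector<int>& pi, std::vector<int>& pj) {
  const int n = i1 - i0 + 1, m = j1 - j0 + 1;
  std::vector<double> D((size_t)n * m);
  std::vector<uint8_t> bt((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      const double d = dist_buf(a, i0 + i, b, j0 + j);
      const size_t idx = (size_t)i * m + j;
      if (i == 0 && j == 0) { D[idx] = d; bt[idx] = 0; continue; }
      double best = R_PosInf; uint8_t step = 0;
      if (i > 0 && j > 0) { best = D[idx - m - 1]; step = 0; }
      if (i > 0 && D[idx - m] < best) { best = D[idx - m]; step = 1; }
      if (j > 0 && D[idx - 1] < best) { best = D[idx - 1]; step = 2; }
      D[idx] = d + best; bt[idx] = step;
    }
  std::vector<int> ri, rj;
  int i = n - 1, j = m - 1;
  while (true) {
    ri.push_back(i0 + i); rj.push_back(j0 + j);
    if (i == 0 && j == 0) break;
    const uint8_t s = bt[(size_t)i * m + j];
    if (s == 0) { --i; --j; } else if (s == 1) { --i; } else { --j; }
  }
  const int L = (int)ri.size();
  for (int k = L - 1 - (skip_first ? 1 : 0); k >= 0; --k) {
    pi.push_back(ri[k]); pj.push_back(rj[k]);
  }
}

static const int DC_BASE = 64;   // below this, fall back to full DP blocks

static void dc_path(const SeqBuf& a, const SeqBuf& b,
                    int i0, int i1, int j0, int j1, bool skip_first,
                    std::vector<int>& pi, std::vector<int>& pj) {
  const int n = i1 - i0 + 1, m = j1 - j0 + 1;
  if ((double)n * m <= (double)DC_BASE * DC_BASE || n <= 2) {
    solve_block(a, b, i0, i1, j0, j1, skip_first, pi, pj);
    return;
  }
  const int mid = i0 + (i1 - i0) / 2;
  std::vector<double> f, g;
  fwd_row(a, b, i0, mid, j0, j1, f);
  bwd_row(a, b, mid, i1, j0, j1, g);
  int bestj = 0; double best = R_PosInf;
  for (int j = 0; j < m; ++j) {
    const double tot = f[j] + g[j] - dist_buf(a, mid, b, j0 + j);
    if (tot < best) { best = tot; bestj = j; }
  }
  const int jm = j0 + bestj;
  dc_path(a, b, i0, mid, j0, jm, skip_first, pi, pj);
  dc_path(a, b, mid, i1, jm, j1, true, pi, pj);
}

// [[Rcpp::export(name = ".dtw_lowmem_cpp")]]
List dtw_lowmem_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("dtw: empty sequence");
  if (a.ncol() != b.ncol()) stop("dtw: feature dimensions differ");
  g_workspace_cells = 0;
  SeqBuf ab(a), bb(b);
  std::vector<int> pi, pj;
  pi.reserve(n + m); pj.reserve(n + m);
  dc_path(ab, bb, 0, n - 1, 0, m - 1, false, pi, pj);
  double cost = 0.0;
  for (size_t k = 0; k < pi.size(); ++k)
    cost += dist_buf(ab, pi[k], bb, pj[k]);
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) { path(k, 0) = pi[k] + 1; path(k, 1) = pj[k] + 1; }
  return List::create(_["cost"] = cost, _["path"] = path,
                      _["workspace_cells"] = (double)g_workspace_cells);
}
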