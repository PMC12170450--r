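#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Epsilon-SVR via SMO on the standard 2n-variable dual with a precomputed
// kernel matrix (the LIBSVM formulation):
//   min_a 0.5 a' Qhat a + p' a,  0 <= a_i <= C,  sum_i s_i a_i = 0
// where a stacks (alpha, alpha*), s_i = +1 for i < n and -1 otherwise,
// Qhat_ij = s_i s_j K(ti, tj) with ti = i mod n, and
// p_i = eps - y_ti (i < n), p_i = eps + y_ti (i >= n).
// The fitted coefficients are beta = alpha - alpha*, and the regression
// function is f(x) = sum_i beta_i K(x_i, x) + b.
//
// Working-set selection is the maximal-violating-pair rule; termination when
// the KKT gap drops below tol. Columns of Y are solved independently so a
// permutation batch reuses one kernel matrix.

static void solve_one(const double* K, int n, const double* y,
                      double C, double eps, double tol, int max_iter,
                      double* beta_out, double* b_out, int* iter_out) {
  const int m = 2 * n;
  std::vector<double> a(m, 0.0);   // stacked alpha, alpha*
  std::vector<double> G(m);        // gradient: Qhat a + p
  for (int i = 0; i < n; ++i) {
    G[i] = eps - y[i];
    G[i + n] = eps + y[i];
  }
  int it = 0;
  for (; it < max_iter; ++it) {
    // maximal violating pair over -s_i G_i
    int iu = -1, il = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int i = 0; i < m; ++i) {
      double s = (i < n) ? 1.0 : -1.0;
      double v = -s * G[i];
      bool up = (s > 0) ? (a[i] < C) : (a[i] > 0);
      bool lo = (s > 0) ? (a[i] > 0) : (a[i] < C);
      if (up && v > gmax) { gmax = v; iu = i; }
      if (lo && v < gmin) { gmin = v; il = i; }
    }
    if (iu < 0 || il < 0 || gmax - gmin < tol) break;

    int ti = iu % n, tj = il % n;
    double si = (iu < n) ? 1.0 : -1.0, sj = (il < n) ? 1.0 : -1.0;
    // curvature along the feasible direction (s_i a_iu += t, s_j a_il -= t)
    double quad = K[ti + n * ti] + K[tj + n * tj] - 2.0 * K[ti + n * tj];
    if (quad <= 1e-12) quad = 1e-12;
    // move delta along (iu: +s_i, il: -s_j) keeping the equality constraint
    double delta = (gmax - gmin) / quad;
    // box clipping
    double max_i = (si > 0) ? (C - a[iu]) : a[iu];
    double max_j = (sj > 0) ? a[il] : (C - a[il]);
    if (delta > max_i) delta = max_i;
    if (delta > max_j) delta = max_j;
    if (delta <= 0) break;
    a[iu] += si > 0 ? delta : -delta;
    a[il] -= sj > 0 ? delta : -delta;
    // G_k += Qhat[k,iu]*da_iu + Qhat[k,il]*da_il, Qhat[k,i] = s_k s_i K[tk,ti]
    double da_iu = (si > 0) ? delta : -delta;
    double da_il = (sj > 0) ? -delta : delta;
    for (int k = 0; k < m; ++k) {
      double sk = (k < n) ? 1.0 : -1.0;
      int tk = k % n;
      G[k] += sk * (si * K[tk + n * ti] * da_iu + sj * K[tk + n * tj] * da_il);
    }
  }
  // beta and intercept
  std::vector<double> beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[i + n];
  // intercept from free support vectors: f(x_i) = y_i -/+ eps
  double bsum = 0.0; int bcnt = 0;
  double blo = -HUGE_VAL, bhi = HUGE_VAL;
  for (int i = 0; i < n; ++i) {
    double fi = 0.0;
    for (int k = 0; k < n; ++k) fi += beta[k] * K[k + n * i];
    if (a[i] > 1e-12 && a[i] < C - 1e-12) { bsum += y[i] - eps - fi; ++bcnt; }
    else if (a[i + n] > 1e-12 && a[i + n] < C - 1e-12) { bsum += y[i] + eps - fi; ++bcnt; }
    else {
      // bound constraints bracket b
      if (a[i] <= 1e-12 && a[i + n] <= 1e-12) {
        if (y[i] - eps - fi > blo) blo = y[i] - eps - fi;  // lower? inactive tube
        if (y[i] + eps - fi < bhi) bhi = y[i] + eps - fi;
      }
    }
  }
  double b;
  if (bcnt > 0) b = bsum / bcnt;
  else if (std::isfinite(blo) && std::isfinite(bhi)) b = 0.5 * (blo + bhi);
  else b = 0.0;
  for (int i = 0; i < n; ++i) beta_out[i] = beta[i];
  *b_out = b;
  *iter_out = it;
}

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericMatrix Y, double C, double eps,
                 double tol, int max_iter) {
  int n = K.nrow(), B = Y.ncol();
  if (K.ncol() != n || Y.nrow() != n)
    stop("kernel matrix and outcome dimensions disagree");
  NumericMatrix beta(n, B);
  NumericVector b(B);
  IntegerVector iters(B);
  for (int j = 0; j < B; ++j) {
    int it = 0;
    solve_one(REAL(K), n, &Y(0, j), C, eps, tol, max_iter,
              &beta(0, j), &b[j], &it);
    iters[j] = it;
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["beta"] = beta, _["b"] = b, _["iterations"] = iters);
}

static inline void decode(int lin, const int* d, int* i, int* j, int* k) {
  *i = lin % d[0];
  *j = (lin / d[0]) % d[1];
  *k = lin / (d[0] * d[1]);
}

// Face-connected (6-neighbour) component labelling of a 3D logical volume
// given as a flat column-major vector. Labels are 1..n_components, 0 outside.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int nv = d[0] * d[1] * d[2];
  if (mask.size() != nv) stop("mask length does not match dims");
  IntegerVector lab(nv, 0);
  int next = 0;
  std::vector<int> stack;
  for (int v = 0; v < nv; ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    ++next;
    stack.push_back(v);
    lab[v] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i, j, k;
      decode(cur, d, &i, &j, &k);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
          continue;
        int w = ii + d[0] * (jj + d[1] * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Largest suprathreshold face-connected extent for each column of S, where
// row v of S lives at full-grid linear index lin0[v] (0-based). Used for the
// cluster-extent permutation null without allocating per-permutation volumes.
// [[Rcpp::export]]
IntegerVector max_extent_batch_cpp(NumericMatrix S, IntegerVector lin0,
                                   IntegerVector dims, double thr) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int nv = d[0] * d[1] * d[2];
  const int V = S.nrow(), B = S.ncol();
  if (lin0.size() != V) stop("lin0 length does not match S");
  std::vector<int> stamp(nv, -1), seen(nv, -1);
  IntegerVector out(B);
  std::vector<int> stack;
  for (int b = 0; b < B; ++b) {
    for (int v = 0; v < V; ++v)
      if (S(v, b) >= thr) stamp[lin0[v]] = b;
    int best = 0;
    for (int v = 0; v < V; ++v) {
      int start = lin0[v];
      if (stamp[start] != b || seen[start] == b) continue;
      int size = 0;
      stack.push_back(start);
      seen[start] = b;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        ++size;
        int i, j, k;
        decode(cur, d, &i, &j, &k);
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int t = 0; t < 6; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
            continue;
          int w = ii + d[0] * (jj + d[1] * kk);
          if (stamp[w] == b && seen[w] != b) { seen[w] = b; stack.push_back(w); }
        }
      }
      if (size > best) best = size;
    }
    out[b] = best;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
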