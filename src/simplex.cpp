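#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dense bounded-variable two-phase primal simplex.
//
//   maximize c'x  subject to  A x = b,  lb <= x <= ub
//
// Lower bounds must be finite (flux bounds in practice are); upper bounds may
// be +Inf, in which case an unblocked improving direction is reported as
// status "unbounded". Anti-cycling: Dantzig pricing switches to Bland's rule
// after a burn-in of degenerate-prone iterations.
//
// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit

static const double EPS_RC = 1e-7;   // reduced-cost entering tolerance
static const double EPS_PIV = 1e-9;  // pivot element tolerance
static const double EPS_FEAS = 1e-7; // phase-1 residual tolerance

struct Tableau {
  int m, n;                  // rows, structural columns (incl. artificials)
  std::vector<double> M;     // m x n row-major: current B^{-1} A
  std::vector<double> beta;  // current values of basic variables
  std::vector<int> basis;    // basis[i] = column basic in row i
  std::vector<int> atUpper;  // nonbasic position flag per column (0 lower, 1 upper)
  std::vector<int> inBasis;  // per column
  std::vector<double> up;    // upper bounds of shifted variables (>= 0, may be Inf)

  double &at(int i, int j) { return M[(size_t)i * n + j]; }
};

// one simplex phase on the prepared tableau; obj maximized
static int run_phase(Tableau &T, const std::vector<double> &cost,
                     int maxit, int &iter_total) {
  const int m = T.m, n = T.n;
  std::vector<double> y(m), d(n);
  int bland_after = 50 * (m + n) + 200;

  for (int iter = 0; iter < maxit; ++iter, ++iter_total) {
    bool bland = iter_total > bland_after;
    // y = c_B' * M  (M already is B^{-1}A, so reduced cost d = c - y)
    for (int j = 0; j < n; ++j) d[j] = cost[j];
    for (int i = 0; i < m; ++i) {
      double cb = cost[T.basis[i]];
      if (cb != 0.0) {
        const double *row = &T.M[(size_t)i * n];
        for (int j = 0; j < n; ++j) d[j] -= cb * row[j];
      }
    }
    // entering variable: improving direction given its current bound
    int q = -1, tdir = 0;
    double best = EPS_RC;
    for (int j = 0; j < n; ++j) {
      if (T.inBasis[j]) continue;
      double dj = d[j];
      int t = 0;
      if (dj > EPS_RC && !T.atUpper[j] && T.up[j] > 0) t = 1; // at lower, increase
      else if (dj < -EPS_RC && T.atUpper[j]) t = -1;     // at upper, decrease
      if (!t) continue;
      double score = std::fabs(dj);
      if (bland) { q = j; tdir = t; break; }
      if (score > best) { best = score; q = j; tdir = t; }
    }
    if (q < 0) return 0; // optimal

    // ratio test
    double delta = T.up[q]; // bound flip distance (may be Inf)
    int r = -1, leaveAtUpper = 0;
    for (int i = 0; i < m; ++i) {
      double w = tdir * T.at(i, q);
      if (w > EPS_PIV) {
        double lim = T.beta[i] / w;
        if (lim < delta - 1e-12) { delta = lim; r = i; leaveAtUpper = 0; }
        else if (bland && r >= 0 && std::fabs(lim - delta) <= 1e-12 &&
                 T.basis[i] < T.basis[r]) { r = i; leaveAtUpper = 0; }
      } else if (w < -EPS_PIV) {
        double ubi = T.up[T.basis[i]];
        if (!std::isfinite(ubi)) continue;
        double lim = (ubi - T.beta[i]) / (-w);
        if (lim < delta - 1e-12) { delta = lim; r = i; leaveAtUpper = 1; }
        else if (bland && r >= 0 && std::fabs(lim - delta) <= 1e-12 &&
                 T.basis[i] < T.basis[r]) { r = i; leaveAtUpper = 1; }
      }
    }
    if (r < 0 && !std::isfinite(delta)) return 2; // unbounded
    if (delta < 0) delta = 0;

    // move entering variable by tdir * delta
    for (int i = 0; i < m; ++i) T.beta[i] -= tdir * delta * T.at(i, q);

    if (r < 0) { // bound flip, no basis change
      T.atUpper[q] = tdir > 0 ? 1 : 0;
      continue;
    }
    int p = T.basis[r];
    double newval = (T.atUpper[q] ? T.up[q] : 0.0) + tdir * delta;
    // pivot row r on column q
    double piv = T.at(r, q);
    double *rowr = &T.M[(size_t)r * n];
    for (int j = 0; j < n; ++j) rowr[j] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == r) continue;
      double f = T.at(i, q);
      if (f != 0.0) {
        double *rowi = &T.M[(size_t)i * n];
        for (int j = 0; j < n; ++j) rowi[j] -= f * rowr[j];
      }
    }
    T.basis[r] = q;
    T.beta[r] = newval;
    T.inBasis[q] = 1; T.atUpper[q] = 0;
    T.inBasis[p] = 0; T.atUpper[p] = leaveAtUpper;
    // clamp tiny negatives from round-off
    for (int i = 0; i < m; ++i) if (T.beta[i] < 0 && T.beta[i] > -1e-9) T.beta[i] = 0;
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericMatrix A, NumericVector b, NumericVector c,
                   NumericVector lb, NumericVector ub,
                   int maxit = 20000) {
  const int m = A.nrow(), nv = A.ncol();
  for (int j = 0; j < nv; ++j) {
    if (!std::isfinite(lb[j]))
      stop("simplex: lower bounds must be finite (variable %d)", j + 1);
    if (ub[j] < lb[j]) stop("simplex: ub < lb for variable %d", j + 1);
  }

  Tableau T;
  T.m = m; T.n = nv + m;
  T.M.assign((size_t)T.m * T.n, 0.0);
  T.beta.assign(m, 0.0);
  T.basis.resize(m);
  T.atUpper.assign(T.n, 0);
  T.inBasis.assign(T.n, 0);
  T.up.resize(T.n);

  // shift x = y + lb;  A y = b - A lb,  0 <= y <= ub - lb
  std::vector<double> b0(m);
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int j = 0; j < nv; ++j) s -= A(i, j) * lb[j];
    b0[i] = s;
  }
  for (int j = 0; j < nv; ++j)
    T.up[j] = std::isfinite(ub[j]) ? ub[j] - lb[j] : std::numeric_limits<double>::infinity();

  for (int i = 0; i < m; ++i) {
    double sgn = b0[i] < 0 ? -1.0 : 1.0;
    for (int j = 0; j < nv; ++j) T.at(i, j) = sgn * A(i, j);
    T.at(i, nv + i) = 1.0;
    T.beta[i] = sgn * b0[i];
    T.basis[i] = nv + i;
    T.inBasis[nv + i] = 1;
    T.up[nv + i] = std::numeric_limits<double>::infinity();
  }

  int iter_total = 0;
  // phase 1: maximize -sum(artificials)
  std::vector<double> c1(T.n, 0.0);
  for (int i = 0; i < m; ++i) c1[nv + i] = -1.0;
  int st = run_phase(T, c1, maxit, iter_total);
  double art = 0.0;
  for (int i = 0; i < m; ++i) if (T.basis[i] >= nv) art += T.beta[i];
  if (st == 3) return List::create(_["status"] = 3);
  if (art > EPS_FEAS) return List::create(_["status"] = 1);

  // phase 2: fix artificials at zero, maximize the true objective
  for (int j = nv; j < T.n; ++j) T.up[j] = 0.0;
  std::vector<double> c2(T.n, 0.0);
  for (int j = 0; j < nv; ++j) c2[j] = c[j];
  st = run_phase(T, c2, maxit, iter_total);
  if (st == 1) st = 0; // cannot happen; keep optimal semantics

  NumericVector x(nv);
  for (int j = 0; j < nv; ++j) x[j] = T.atUpper[j] && std::isfinite(T.up[j]) ? T.up[j] : 0.0;
  for (int i = 0; i < m; ++i) if (T.basis[i] < nv) x[T.basis[i]] = T.beta[i];
  double obj = 0.0;
  for (int j = 0; j < nv; ++j) { x[j] += lb[j]; obj += c[j] * x[j]; }
  return List::create(_["status"] = st, _["objective"] = obj, _["x"] = x,
                      _["iterations"] = iter_total);
}
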