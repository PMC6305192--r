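// Bounded-variable two-phase primal simplex for the flux LPs.
//
// Solves   min c'x   s.t.  A x = b,  l <= x <= u   (l, u finite on the
// structural variables; flux bounds are always finite in this package).
// Dense arithmetic is adequate at the model sizes handled here (tens to a
// few hundred reactions); the basis system is re-solved each iteration
// rather than maintained as a factorization.
//
// Status codes: 0 optimal, 1 infeasible, 2 iteration limit, 3 unbounded,
// 4 numerical failure (singular basis).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const double TOL_DJ   = 1e-9;   // reduced-cost optimality tolerance
const double TOL_PIV  = 1e-10;  // pivot magnitude tolerance
const double TOL_FEAS = 1e-7;   // phase-1 residual tolerance

struct SimplexState {
  mat A;            // m x N (structural + artificial columns)
  vec c, l, u, x;
  ivec basis;       // m basic column indices
  // 0 = basic, 1 = nonbasic at lower, 2 = nonbasic at upper
  ivec where;
  int m, N;
};

// One simplex run with the current cost vector. Returns status.
int run_simplex(SimplexState &st, int maxiter) {
  const int m = st.m, N = st.N;
  int bland_after = 4 * (N + m);

  for (int iter = 0; iter < maxiter; ++iter) {
    mat B = st.A.cols(conv_to<uvec>::from(st.basis));
    vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = st.c[st.basis[i]];

    vec y;
    bool ok = solve(y, B.t(), cB, solve_opts::no_approx);
    if (!ok) return 4;

    // pricing
    int q = -1;
    double best = TOL_DJ;
    bool bland = iter > bland_after;
    for (int j = 0; j < N; ++j) {
      if (st.where[j] == 0) continue;
      if (st.u[j] - st.l[j] <= 0) continue;  // fixed variable cannot move
      double dj = st.c[j] - dot(st.A.col(j), y);
      double viol = 0.0;
      if (st.where[j] == 1 && dj < -TOL_DJ) viol = -dj;
      if (st.where[j] == 2 && dj >  TOL_DJ) viol =  dj;
      if (viol > 0.0) {
        if (bland) { q = j; break; }
        if (viol > best) { best = viol; q = j; }
      }
    }
    if (q < 0) return 0;  // optimal

    double sigma = (st.where[q] == 1) ? 1.0 : -1.0;
    vec w;
    ok = solve(w, B, st.A.col(q), solve_opts::no_approx);
    if (!ok) return 4;

    // ratio test; bound flip of the entering variable competes
    double t = st.u[q] - st.l[q];  // may be inf
    int leave = -1;                // -1 => bound flip
    double leave_piv = 0.0;
    for (int i = 0; i < m; ++i) {
      double delta = -sigma * w[i];
      int bi = st.basis[i];
      double ti;
      if (delta > TOL_PIV)       ti = (st.u[bi] - st.x[bi]) / delta;
      else if (delta < -TOL_PIV) ti = (st.l[bi] - st.x[bi]) / delta;
      else continue;
      if (ti < -1e-12) ti = 0.0;
      // ties: largest pivot for stability; lowest index in Bland mode
      bool better = ti < t - 1e-12 ||
        (ti < t + 1e-12 &&
         (bland ? (leave < 0 || st.basis[i] < st.basis[leave])
                : std::abs(delta) > leave_piv));
      if (better) { t = ti; leave = i; leave_piv = std::abs(delta); }
    }
    if (!std::isfinite(t)) return 3;  // unbounded
    if (t < 0) t = 0;

    // update values
    double from = (st.where[q] == 1) ? st.l[q] : st.u[q];
    st.x[q] = from + sigma * t;
    for (int i = 0; i < m; ++i) st.x[st.basis[i]] += -sigma * w[i] * t;

    if (leave < 0) {
      // entering variable runs to its opposite bound
      st.where[q] = (st.where[q] == 1) ? 2 : 1;
      st.x[q] = (st.where[q] == 1) ? st.l[q] : st.u[q];
    } else {
      int out = st.basis[leave];
      // leaving variable parks at the bound it hit
      double dl = std::abs(st.x[out] - st.l[out]);
      double du = std::abs(st.x[out] - st.u[out]);
      if (dl <= du) { st.where[out] = 1; st.x[out] = st.l[out]; }
      else          { st.where[out] = 2; st.x[out] = st.u[out]; }
      st.basis[leave] = q;
      st.where[q] = 0;
    }
  }
  return 2;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat &Amat, const arma::vec &bvec,
                         const arma::vec &cvec, const arma::vec &lb,
                         const arma::vec &ub, int maxiter = 20000) {
  const int m = Amat.n_rows, n = Amat.n_cols;
  SimplexState st;
  st.m = m; st.N = n + m;
  st.A.set_size(m, st.N);
  st.A.cols(0, n - 1) = Amat;
  st.c = vec(st.N, fill::zeros);
  st.l = vec(st.N, fill::zeros);
  st.u = vec(st.N, fill::zeros);
  st.x = vec(st.N, fill::zeros);
  st.where.set_size(st.N);
  st.basis.set_size(m);

  // structural variables start at the finite bound nearer zero
  for (int j = 0; j < n; ++j) {
    st.l[j] = lb[j]; st.u[j] = ub[j];
    if (std::abs(lb[j]) <= std::abs(ub[j])) { st.where[j] = 1; st.x[j] = lb[j]; }
    else                                    { st.where[j] = 2; st.x[j] = ub[j]; }
  }
  vec r = bvec - Amat * st.x.subvec(0, n - 1);

  // artificial columns carry the phase-1 residual
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    st.A.col(j).zeros();
    st.A(i, j) = (r[i] >= 0) ? 1.0 : -1.0;
    st.l[j] = 0.0; st.u[j] = datum::inf;
    st.x[j] = std::abs(r[i]);
    st.where[j] = 0;
    st.basis[i] = j;
    st.c[j] = 1.0;
  }

  int status = run_simplex(st, maxiter);
  if (status == 0) {
    double phase1 = 0.0;
    for (int i = n; i < st.N; ++i) phase1 += st.x[i];
    if (phase1 > TOL_FEAS) status = 1;  // infeasible
  }

  if (status == 0) {
    // phase 2: original costs; artificials frozen at zero
    for (int j = 0; j < n; ++j) st.c[j] = cvec[j];
    for (int j = n; j < st.N; ++j) { st.c[j] = 0.0; st.u[j] = 0.0; }
    status = run_simplex(st, maxiter);
  }

  vec x = st.x.subvec(0, n - 1);
  double obj = dot(cvec, x);
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}
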