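// Weighted L1-penalized linear SVM solved as a linear program.
//
// Primal (split-variable form):
//   min  sum_i w_i xi_i + sum_j d_j (beta_j^+ + beta_j^-)
//   s.t. z_i { b0^+ - b0^- + sum_j h_ij (beta_j^+ - beta_j^-) } >= 1 - xi_i
//        all variables >= 0.
//
// Solved through its dual, which has only 2p+1 rows regardless of n:
//   max  1'alpha
//   s.t.  sum_i alpha_i z_i h_ij + s_j = d_j      (j = 1..p)
//        -sum_i alpha_i z_i h_ij + t_j = d_j      (j = 1..p)
//         sum_i alpha_i z_i            = 0
//         0 <= alpha_i <= w_i,  s_j, t_j >= 0.
// The simplex multipliers of the three row blocks at optimality are
// (beta^+, beta^-, b0) of the primal.  The dual is always feasible
// (alpha = 0) and bounded (objective <= sum w), so the LP is always solvable.

#include <RcppArmadillo.h>
using namespace arma;

// bounded-variable revised primal simplex, maximization
// A (m x N), rhs b, bounds [lo, up], costs c; initial basis given,
// all nonbasic variables start at lower bound.
// status: 0 optimal, 1 iteration limit
struct SimplexResult {
  vec x;
  vec y;       // simplex multipliers at optimum
  double obj;
  int status;
  int iters;
};

static SimplexResult bounded_simplex(const mat &A, const vec &b, const vec &c,
                                     const vec &lo, const vec &up,
                                     uvec basis, int max_iter) {
  const uword m = A.n_rows, N = A.n_cols;
  const double tol = 1e-9;

  // at_upper[j]: nonbasic at upper bound
  std::vector<bool> in_basis(N, false), at_upper(N, false);
  for (uword i = 0; i < m; ++i) in_basis[basis(i)] = true;

  vec x(N);
  for (uword j = 0; j < N; ++j) x(j) = lo(j);

  auto recompute_xb = [&](void) {
    vec rhs = b;
    for (uword j = 0; j < N; ++j)
      if (!in_basis[j] && x(j) != 0.0) rhs -= A.col(j) * x(j);
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
    vec xb = solve(B, rhs);
    for (uword i = 0; i < m; ++i) x(basis(i)) = xb(i);
  };
  recompute_xb();

  int iter = 0, stall = 0;
  double last_obj = -datum::inf;
  bool bland = false;
  SimplexResult res;

  while (iter < max_iter) {
    ++iter;
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
    vec cb(m);
    for (uword i = 0; i < m; ++i) cb(i) = c(basis(i));
    vec y = solve(B.t(), cb);

    // pricing
    sword enter = -1;
    double best = tol;
    bool enter_from_upper = false;
    for (uword j = 0; j < N; ++j) {
      if (in_basis[j]) continue;
      double r = c(j) - dot(y, A.col(j));
      bool elig_lo = (!at_upper[j]) && r > tol && up(j) > lo(j);
      bool elig_up = at_upper[j] && r < -tol;
      if (!elig_lo && !elig_up) continue;
      double score = std::fabs(r);
      if (bland) { enter = j; enter_from_upper = elig_up; break; }
      if (score > best) { best = score; enter = j; enter_from_upper = elig_up; }
    }
    if (enter < 0) {  // optimal
      res.x = x; res.y = y;
      res.obj = dot(c, x); res.status = 0; res.iters = iter;
      return res;
    }

    vec dir = solve(B, A.col(enter));
    // entering moves by delta: from lower increase (+), from upper decrease (-)
    double sgn = enter_from_upper ? -1.0 : 1.0;
    // basic variables change by -sgn * dir * delta
    double delta = up(enter) - lo(enter);  // bound-flip limit
    sword leave = -1;
    double leave_bound = 0.0;
    for (uword i = 0; i < m; ++i) {
      double rate = -sgn * dir(i);  // d x_B(i) / d delta
      uword bi = basis(i);
      if (rate < -tol) {
        double room = (x(bi) - lo(bi)) / (-rate);
        if (room < delta - 1e-12) { delta = room; leave = i; leave_bound = lo(bi); }
      } else if (rate > tol) {
        if (std::isfinite(up(bi))) {
          double room = (up(bi) - x(bi)) / rate;
          if (room < delta - 1e-12) { delta = room; leave = i; leave_bound = up(bi); }
        }
      }
    }
    if (!std::isfinite(delta)) {  // unbounded: cannot happen for this LP
      res.x = x; res.y.zeros(m); res.obj = datum::inf;
      res.status = 2; res.iters = iter;
      return res;
    }
    if (delta < 0) delta = 0;

    // apply step
    for (uword i = 0; i < m; ++i) x(basis(i)) -= sgn * dir(i) * delta;
    x(enter) += sgn * delta;

    if (leave < 0) {
      // bound flip, basis unchanged
      at_upper[enter] = !enter_from_upper;
    } else {
      uword out = basis(leave);
      in_basis[out] = false;
      at_upper[out] = (leave_bound == up(out)) && std::isfinite(up(out)) &&
                      up(out) > lo(out);
      x(out) = leave_bound;
      basis(leave) = enter;
      in_basis[enter] = true;
      at_upper[enter] = false;
    }

    double obj = dot(c, x);
    if (obj <= last_obj + 1e-11) ++stall; else { stall = 0; bland = false; }
    last_obj = obj;
    if (stall > 200) bland = true;          // anti-cycling fallback
    if (iter % 256 == 0) recompute_xb();    // refresh against drift
  }

  recompute_xb();
  mat B(m, m);
  for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
  vec cb(m);
  for (uword i = 0; i < m; ++i) cb(i) = c(basis(i));
  res.x = x; res.y = solve(B.t(), cb);
  res.obj = dot(c, x); res.status = 1; res.iters = iter;
  return res;
}

// [[Rcpp::export(name = ".lp_weighted_l1_svm")]]
Rcpp::List lp_weighted_l1_svm(const arma::mat &H, const arma::vec &z,
                              const arma::vec &w, const arma::vec &d,
                              int max_iter = 0) {
  const uword n = H.n_rows, p = H.n_cols;
  const uword m = 2 * p + 1, N = n + 2 * p + 1;
  if (max_iter <= 0) max_iter = 100 * (int)(N + m) + 2000;

  mat A(m, N, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < p; ++j) {
      double v = z(i) * H(i, j);
      A(j, i) = v;
      A(p + j, i) = -v;
    }
    A(2 * p, i) = z(i);
  }
  for (uword j = 0; j < 2 * p; ++j) A(j, n + j) = 1.0;  // slacks s, t
  A(2 * p, N - 1) = 1.0;                                // artificial, fixed at 0

  vec b(m);
  for (uword j = 0; j < p; ++j) { b(j) = d(j); b(p + j) = d(j); }
  b(2 * p) = 0.0;

  vec c(N, fill::zeros);
  c.head(n).ones();

  vec lo(N, fill::zeros), up(N);
  up.head(n) = w;
  for (uword j = 0; j < 2 * p; ++j) up(n + j) = datum::inf;
  up(N - 1) = 0.0;  // artificial pinned to zero

  uvec basis(m);
  for (uword j = 0; j < 2 * p; ++j) basis(j) = n + j;
  basis(2 * p) = N - 1;

  SimplexResult r = bounded_simplex(A, b, c, lo, up, basis, max_iter);

  // primal recovery from the simplex multipliers
  vec bp = r.y.head(p), bm = r.y.subvec(p, 2 * p - 1);
  double b0 = r.y(2 * p);
  vec beta = bp - bm;
  vec f = b0 + H * beta;
  vec xi(n);
  for (uword i = 0; i < n; ++i) xi(i) = std::max(0.0, 1.0 - z(i) * f(i));
  double primal_obj = dot(w, xi) + dot(d, abs(beta));

  return Rcpp::List::create(
      Rcpp::Named("beta0") = b0, Rcpp::Named("beta") = beta,
      Rcpp::Named("xi") = xi, Rcpp::Named("alpha") = r.x.head(n),
      Rcpp::Named("objective") = primal_obj,
      Rcpp::Named("dual_objective") = r.obj, Rcpp::Named("status") = r.status,
      Rcpp::Named("iterations") = r.iters);
}
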