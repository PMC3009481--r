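// Cyclic exact coordinate maximization for the penalized NPCA objective
//   J(U) = 0.5 * sum(U % (A U)) - alpha * ||U'U - I||_F^2 ,  A = X X',
// updating one entry of U at a time.  Restricted to the entry u = U(s,l)
// the objective is the quartic f(u) = -alpha u^4 + c2 u^2 + c1 u + c0 whose
// nonnegative argmax is found in closed form from the roots of the cubic
// derivative.  The cross-term caches M = A U and G = U'U are maintained
// incrementally, giving O(d + k) work per entry.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// argmax over u >= 0 of f(u) = -a u^4 + c2 u^2 + c1 u  (a > 0)
static double argmax_quartic(double a, double c2, double c1) {
  double best_u = 0.0, best_f = 0.0; // f(0) = 0
  // stationary points: u^3 + p u + q = 0
  const double p = -c2 / (2.0 * a);
  const double q = -c1 / (4.0 * a);
  double roots[3];
  int nroots = 0;
  const double disc = q * q / 4.0 + p * p * p / 27.0;
  if (disc > 0.0) {
    const double sq = std::sqrt(disc);
    roots[nroots++] = std::cbrt(-q / 2.0 + sq) + std::cbrt(-q / 2.0 - sq);
  } else if (p < 0.0) {
    const double mm = 2.0 * std::sqrt(-p / 3.0);
    double arg = 3.0 * q / (2.0 * p) * std::sqrt(-3.0 / p);
    arg = std::min(1.0, std::max(-1.0, arg));
    const double theta = std::acos(arg) / 3.0;
    for (int kk = 0; kk < 3; ++kk) {
      roots[nroots++] = mm * std::cos(theta - 2.0 * M_PI * kk / 3.0);
    }
  } // p >= 0 && disc <= 0 only when p == q == 0: root at 0, already covered
  for (int i = 0; i < nroots; ++i) {
    const double u = roots[i];
    if (u > 0.0) {
      const double f = ((-a * u * u + c2) * u + c1) * u;
      if (f > best_f) {
        best_f = f;
        best_u = u;
      }
    }
  }
  return best_u;
}

static double objective_cached(const mat& U, const mat& M, const mat& G,
                               double alpha) {
  const mat D = G - eye(G.n_rows, G.n_cols);
  return 0.5 * accu(U % M) - alpha * accu(D % D);
}

// [[Rcpp::export]]
Rcpp::List coord_descent_cpp(arma::mat U, const arma::mat& A, double alpha,
                             int max_sweeps, double tol) {
  const uword d = U.n_rows, k = U.n_cols;
  mat M = A * U;
  mat G = U.t() * U;
  std::vector<double> trace;
  trace.push_back(objective_cached(U, M, G, alpha));
  bool converged = false;
  int sweeps = 0;
  for (int sw = 0; sw < max_sweeps; ++sw) {
    for (uword s = 0; s < d; ++s) {
      const double Ass = A(s, s);
      for (uword l = 0; l < k; ++l) {
        const double u0 = U(s, l);
        const double rowdot = dot(U.row(s), U.row(s));
        const double c_ll = G(l, l) - u0 * u0;
        const double m1 = M(s, l) - Ass * u0;
        const double c2 = Ass / 2.0 - 2.0 * alpha * (c_ll - 1.0) -
          2.0 * alpha * (rowdot - u0 * u0);
        const double cross = dot(U.row(s), G.col(l)) - u0 * rowdot -
          u0 * c_ll;
        const double c1 = m1 - 4.0 * alpha * cross;
        const double unew = argmax_quartic(alpha, c2, c1);
        if (unew != u0) {
          const double delta = unew - u0;
          U(s, l) = unew;
          M.col(l) += A.col(s) * delta;
          const rowvec upd = delta * U.row(s);
          G.col(l) += upd.t();
          G.row(l) += upd;
          G(l, l) -= delta * delta; // correct the doubly-updated diagonal
        }
      }
    }
    sweeps = sw + 1;
    if (sweeps % 50 == 0) { // refresh caches against numerical drift
      M = A * U;
      G = U.t() * U;
    }
    trace.push_back(objective_cached(U, M, G, alpha));
    // KKT residual: at entries clipped to zero only an ascent direction
    // (positive gradient) counts as unconverged
    mat grad = M + 4.0 * alpha * (U - U * G);
    grad.elem(find(U == 0.0 && grad < 0.0)).zeros();
    if (norm(grad, "fro") <= tol) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("U") = U,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_sweeps") = sweeps,
    Rcpp::Named("converged") = converged);
}
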