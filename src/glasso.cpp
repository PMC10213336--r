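// Graphical lasso by block coordinate descent (Friedman-style), with an
// off-diagonal-only L1 penalty and warm-started penalty paths.
//
// The solver ascends the dual: maximise log det W subject to
// |W_ij - S_ij| <= lambda for i != j and W_ii = S_ii.  Each column update
// solves its block subproblem exactly via an inner lasso coordinate descent,
// so log det W is non-decreasing across sweeps (returned as a trace).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for: min 0.5 b'W11 b - s12'b + lambda ||b||_1
static void lasso_cd(const mat &W11, const vec &s12, double lambda, vec &beta,
                     int maxit, double tol) {
  const uword m = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double del = 0.0;
    for (uword k = 0; k < m; ++k) {
      double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
      double bnew = 0.0;
      if (r > lambda)
        bnew = (r - lambda) / W11(k, k);
      else if (r < -lambda)
        bnew = (r + lambda) / W11(k, k);
      double d = std::fabs(bnew - beta(k));
      if (d > del) del = d;
      beta(k) = bnew;
    }
    if (del < tol) break;
  }
}

struct GlassoOut {
  mat W;
  mat K;
  bool converged;
  int iter;
  vec logdet_trace;
};

static GlassoOut glasso_core(const mat &S, double lambda, double tol,
                             int maxit, const mat &W_start, bool trace) {
  const uword p = S.n_rows;
  mat W = W_start;
  mat B(p - 1, p, fill::zeros); // column j holds beta for block j

  // scale for the convergence test: mean |off-diagonal of S|
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) sbar += std::fabs(S(i, j));
  sbar /= (double)(p * (p - 1));
  double thresh = (sbar > 0.0) ? tol * sbar : tol;
  double inner_tol = thresh * 0.1;
  if (inner_tol < 1e-12) inner_tol = 1e-12;

  std::vector<double> ld;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    double change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword t = 0;
      for (uword i = 0; i < p; ++i)
        if (i != j) idx(t++) = i;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      lasso_cd(W11, s12, lambda, beta, 1000, inner_tol);
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword t2 = 0; t2 < p - 1; ++t2) {
        change += std::fabs(W(idx(t2), j) - w12(t2));
        W(idx(t2), j) = w12(t2);
        W(j, idx(t2)) = w12(t2);
      }
    }
    change /= (double)(p * (p - 1));
    if (trace) {
      double v, sign;
      log_det(v, sign, W);
      ld.push_back(v);
    }
    if (change < thresh) {
      converged = true;
      break;
    }
  }

  // recover K from the final betas: k22 = 1/(w22 - w12' beta), k12 = -beta*k22
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword t = 0;
    for (uword i = 0; i < p; ++i)
      if (i != j) idx(t++) = i;
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double k22 = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = k22;
    for (uword t2 = 0; t2 < p - 1; ++t2) K(idx(t2), j) = -beta(t2) * k22;
  }
  K = 0.5 * (K + K.t());

  GlassoOut out;
  out.W = W;
  out.K = K;
  out.converged = converged;
  out.iter = iter > maxit ? maxit : iter;
  out.logdet_trace = vec(ld);
  return out;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat &S, double lambda, double tol, int maxit,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      bool trace = false) {
  mat W0;
  if (W_init.isNotNull())
    W0 = Rcpp::as<mat>(Rcpp::NumericMatrix(W_init));
  else {
    W0 = S;
  }
  GlassoOut o = glasso_core(S, lambda, tol, maxit, W0, trace);
  return Rcpp::List::create(
      Rcpp::Named("W") = o.W, Rcpp::Named("K") = o.K,
      Rcpp::Named("converged") = o.converged, Rcpp::Named("iter") = o.iter,
      Rcpp::Named("logdet_trace") = o.logdet_trace);
}

// Warm-started path over a decreasing lambda sequence.  Returns, per lambda,
// the precision estimate plus the pieces EBIC needs (log det K, tr(SK)).
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat &S, const arma::vec &lambdas,
                           double tol, int maxit) {
  const uword nl = lambdas.n_elem;
  const uword p = S.n_rows;
  Rcpp::List Ks(nl);
  Rcpp::LogicalVector conv(nl);
  Rcpp::NumericVector logdetK(nl), trSK(nl);
  mat W = S;
  for (uword l = 0; l < nl; ++l) {
    GlassoOut o = glasso_core(S, lambdas(l), tol, maxit, W, false);
    W = o.W; // warm start for the next (smaller) lambda
    Ks[l] = Rcpp::wrap(o.K);
    conv[l] = o.converged;
    double v, sign;
    bool ok = log_det(v, sign, o.K);
    logdetK[l] = (ok && sign > 0) ? v : NA_REAL;
    trSK[l] = trace(S * o.K);
    (void)p;
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks, Rcpp::Named("converged") = conv,
                            Rcpp::Named("logdetK") = logdetK,
                            Rcpp::Named("trSK") = trSK);
}
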