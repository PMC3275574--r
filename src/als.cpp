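#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve a small least-squares system, falling back to the pseudoinverse
// when the normal equations are singular (possible for degenerate patterns
// or fewer conditions than regulators).
static vec safe_solve(const mat& G, const vec& b) {
  vec x;
  bool ok = solve(x, G, b, solve_opts::no_approx);
  if (!ok) x = pinv(G) * b;
  return x;
}

// Alternating least squares for the pattern-constrained bilinear model
// E ~ A * P with A zero outside `mask`.  One iteration is a P-step
// (unconstrained LS given A) followed by a per-gene A-step restricted to
// each gene's regulator set.
//
// `ridge` >= 0 adds a Tikhonov penalty ridge * (||A||_F^2 + ||P||_F^2) / 2
// to the squared Frobenius loss; both half-steps then minimize the same
// penalized objective exactly, so the penalized objective is non-increasing
// by construction (and with ridge = 0 the raw residual is).  The penalty
// suppresses near-cancelling column pairs that plain ALS can drift into
// when two TFs share target genes and the data hold no signal to separate
// them.  Iteration stops when the residual change, relative to ||E||_F,
// falls below `tol`, or when the residual is numerically zero.
// [[Rcpp::export]]
Rcpp::List als_engine(const arma::mat& E, const arma::umat& mask, arma::mat A,
                      double tol, int max_iter, double ridge = 0.0) {
  const uword n_genes = E.n_rows, n_tfs = mask.n_cols;
  const double normE = norm(E, "fro");

  std::vector<uvec> reg(n_genes);
  for (uword g = 0; g < n_genes; ++g) reg[g] = find(mask.row(g).t());

  mat P(n_tfs, E.n_cols, fill::zeros);
  const mat I_tf = eye(n_tfs, n_tfs);
  double r_prev = datum::inf, r = normE;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    // P-step
    mat G = A.t() * A + ridge * I_tf;
    bool ok = solve(P, G, A.t() * E, solve_opts::no_approx);
    if (!ok) P = pinv(G) * (A.t() * E);

    // A-step, gene by gene over each gene's regulator set
    for (uword g = 0; g < n_genes; ++g) {
      const uvec& idx = reg[g];
      if (idx.n_elem == 0) continue;
      mat Ps = P.rows(idx);
      mat Gg = Ps * Ps.t() + ridge * eye(idx.n_elem, idx.n_elem);
      vec a = safe_solve(Gg, Ps * E.row(g).t());
      for (uword j = 0; j < idx.n_elem; ++j) A(g, idx[j]) = a[j];
    }

    r = norm(E - A * P, "fro");
    if (std::abs(r_prev - r) < tol * std::max(normE, 1e-300) ||
        r <= 1e-13 * normE) {
      converged = true;
      break;
    }
    r_prev = r;
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("P") = P,
                            Rcpp::Named("residual") = r,
                            Rcpp::Named("n_iter") = it,
                            Rcpp::Named("converged") = converged);
}

// Per-gene least-squares control strengths against a fixed activity matrix
// P, restricted to each gene's regulator set.  Used for null refits during
// trimming, where only a gene's expression row changes.
// [[Rcpp::export]]
arma::mat gene_strengths(const arma::mat& E, const arma::umat& mask,
                         const arma::mat& P) {
  const uword n_genes = E.n_rows, n_tfs = mask.n_cols;
  mat A(n_genes, n_tfs, fill::zeros);
  for (uword g = 0; g < n_genes; ++g) {
    uvec idx = find(mask.row(g).t());
    if (idx.n_elem == 0) continue;
    mat Ps = P.rows(idx);
    vec a = safe_solve(Ps * Ps.t(), Ps * E.row(g).t());
    for (uword j = 0; j < idx.n_elem; ++j) A(g, idx[j]) = a[j];
  }
  return A;
}
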