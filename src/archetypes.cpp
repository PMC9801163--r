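// Numerical core for archetype / archetypoid analysis.
//
// Every operation here reduces to simplex-constrained least squares:
// minimise ||t - w'B||^2 subject to w >= 0, sum(w) = 1. It is solved as
// Lawson-Hanson active-set NNLS on a system augmented with a sum-to-one
// row scaled by 200 * ||t||_inf, followed by exact renormalisation.
// These solvers are called O(N * n) times by the subsampled archetypoid
// search, hence compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x >= 0.
// The passive set stays small (<= rank of A, here <= n_indicators + 1), so
// each inner solve is a tiny least-squares problem even when q is large.
static vec nnls_solve(const mat& A, const vec& b, const int max_outer = 10 * 30) {
  const uword q = A.n_cols;
  vec x(q, fill::zeros);
  std::vector<bool> passive(q, false);
  // dual-feasibility tolerance on the gradient A'(b - Ax); scaled by ||b||
  // only — scaling by matrix norms breaks down for wide basis matrices
  const double wtol = 1e-10 * std::max(1.0, norm(b));

  int outer = 0;
  while (outer++ < max_outer) {
    vec w = A.t() * (b - A * x);
    // most violating coordinate among the active (zero) set
    double wmax = wtol;
    sword t = -1;
    for (uword j = 0; j < q; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (sword)j; }
    }
    if (t < 0) break;
    passive[(uword)t] = true;

    // inner loop: restore feasibility of the passive-set LS solution
    for (int inner = 0; inner < max_outer; ++inner) {
      uvec P(q); uword np = 0;
      for (uword j = 0; j < q; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      if (!solve(z, A.cols(P), b)) {
        // rank-deficient passive set: fall back to pinv
        z = pinv(A.cols(P)) * b;
      }
      if (z.min() > 1e-12) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step back along the segment x -> z until the first coordinate hits 0
      double alpha = datum::inf;
      for (uword jj = 0; jj < np; ++jj) {
        if (z(jj) <= 1e-12) {
          double xa = x(P(jj));
          double denom = xa - z(jj);
          if (denom > 0) alpha = std::min(alpha, xa / denom);
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword jj = 0; jj < np; ++jj) {
        double xn = x(P(jj)) + alpha * (z(jj) - x(P(jj)));
        x(P(jj)) = xn;
        if (xn <= 1e-12) { x(P(jj)) = 0.0; passive[P(jj)] = false; }
      }
    }
  }
  return x;
}

// Simplex-constrained LS of one target against the rows of a basis whose
// transpose (plus a scale row) is passed pre-allocated in `aug`.
// aug is (m+1) x k with the first m rows fixed to basis^T; the last row and
// the rhs are set here from the target.
static vec simplex_weights_aug(mat& aug, const rowvec& target) {
  const uword m = aug.n_rows - 1, k = aug.n_cols;
  // floor the scale so the sum-to-one row keeps weight for near-zero targets
  double s = 200.0 * std::max(1.0, norm(target, "inf"));
  aug.row(m).fill(s);
  vec b(m + 1);
  b.subvec(0, m - 1) = target.t();
  b(m) = s;
  vec x = nnls_solve(aug, b);
  double tot = accu(x);
  if (tot <= 0 || !std::isfinite(tot)) {
    x.fill(1.0 / (double)k);
  } else {
    x /= tot;
  }
  return x;
}

// NNLS via the normal equations: minimise (1/2) x'Gx - c'x subject to x >= 0,
// with G = B B' SPD. The k x k Gram is precomputed once per basis, so the
// per-target cost is a handful of tiny symmetric solves — this is the hot
// path of candidate-set scoring in the subsampled search.
static vec nnls_gram(const mat& G, const vec& c, const double wtol) {
  const uword q = G.n_cols;
  vec x(q, fill::zeros);
  std::vector<bool> passive(q, false);
  const int max_outer = 10 * (int)q + 30;

  int outer = 0;
  while (outer++ < max_outer) {
    vec w = c - G * x;
    double wmax = wtol;
    sword t = -1;
    for (uword j = 0; j < q; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (sword)j; }
    }
    if (t < 0) break;
    passive[(uword)t] = true;

    for (int inner = 0; inner < max_outer; ++inner) {
      uvec P(q); uword np = 0;
      for (uword j = 0; j < q; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      if (!solve(z, G.submat(P, P), c(P),
                 solve_opts::likely_sympd + solve_opts::no_approx)) {
        z = pinv(G.submat(P, P)) * c(P);
      }
      if (z.min() > 1e-12) {
        x.zeros();
        x(P) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword jj = 0; jj < np; ++jj) {
        if (z(jj) <= 1e-12) {
          double xa = x(P(jj));
          double denom = xa - z(jj);
          if (denom > 0) alpha = std::min(alpha, xa / denom);
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword jj = 0; jj < np; ++jj) {
        double xn = x(P(jj)) + alpha * (z(jj) - x(P(jj)));
        x(P(jj)) = xn;
        if (xn <= 1e-12) { x(P(jj)) = 0.0; passive[P(jj)] = false; }
      }
    }
  }
  return x;
}

// Batch simplex-LS of every row of X against archetypes Z via the Gram path.
// The sum-to-one row uses one batch-wide scale (200 * max(1, ||X||_inf)),
// which is an equivalent penalty device to a per-target scale given the
// exact renormalisation that follows.
static void alphas_into(const mat& X, const mat& Z, mat& A, vec& resid) {
  const uword n = X.n_rows, k = Z.n_rows;
  const double s = 200.0 * std::max(1.0, std::max(norm(vectorise(X), "inf"),
                                                  norm(vectorise(Z), "inf")));
  const double s2 = s * s;
  mat G = Z * Z.t() + s2 * ones(k, k);
  mat C = Z * X.t();          // k x n
  C.each_col() += vec(k, fill::value(s2));
  const double wtol = 1e-8 * s; // gradient entries scale with s^2 * residual/s
  A.set_size(n, k);
  resid.set_size(n);
  for (uword i = 0; i < n; ++i) {
    vec x = nnls_gram(G, C.col(i), wtol);
    double tot = accu(x);
    vec w = (tot > 0 && std::isfinite(tot)) ? vec(x / tot)
                                            : vec(k, fill::value(1.0 / k));
    A.row(i) = w.t();
    rowvec r = X.row(i) - w.t() * Z;
    resid(i) = dot(r, r);
  }
}

// Optimal alpha rows of X against archetypes Z, plus per-row squared residuals.
// [[Rcpp::export]]
Rcpp::List cpp_alphas(const arma::mat& X, const arma::mat& Z) {
  mat A;
  vec resid;
  alphas_into(X, Z, A, resid);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("resid") = resid);
}

static double subset_rss(const mat& X, const uvec& idx) {
  mat A;
  vec resid;
  alphas_into(X, X.rows(idx), A, resid);
  return accu(resid);
}

// Full-data RSS of each candidate archetypoid index set (0-based rows of `sets`).
// [[Rcpp::export]]
arma::vec cpp_score_subsets(const arma::mat& X, const arma::umat& sets) {
  vec out(sets.n_rows);
  for (uword s = 0; s < sets.n_rows; ++s) {
    out(s) = subset_rss(X, sets.row(s).t());
  }
  return out;
}

// [[Rcpp::export]]
double cpp_subset_rss(const arma::mat& X, const arma::uvec& idx) {
  return subset_rss(X, idx);
}

// PAM-style SWAP: best-improvement exchanges between selected and unselected
// rows until no exchange improves RSS by more than rel_tol (relative), or
// max_sweeps elapse. Ties break toward the lowest candidate row index.
// [[Rcpp::export]]
Rcpp::List cpp_swap_phase(const arma::mat& X, const arma::uvec& idx0,
                          const double rel_tol, const int max_sweeps) {
  const uword n = X.n_rows, k = idx0.n_elem;
  uvec idx = idx0;
  double cur = subset_rss(X, idx);
  std::vector<double> tr_rss;
  std::vector<int> tr_sweep, tr_out, tr_in;

  for (int sweep = 1; sweep <= max_sweeps; ++sweep) {
    if (cur <= 0) break;
    std::vector<bool> selected(n, false);
    for (uword j = 0; j < k; ++j) selected[idx(j)] = true;

    double best = cur;
    sword best_j = -1, best_r = -1;
    for (uword r = 0; r < n; ++r) {
      if (selected[r]) continue;
      for (uword j = 0; j < k; ++j) {
        uvec cand = idx;
        cand(j) = r;
        double val = subset_rss(X, cand);
        if (val < best) { best = val; best_j = (sword)j; best_r = (sword)r; }
      }
    }
    if (best_j < 0 || (cur - best) <= rel_tol * cur) break;
    tr_sweep.push_back(sweep);
    tr_out.push_back((int)idx((uword)best_j));
    tr_in.push_back((int)best_r);
    idx((uword)best_j) = (uword)best_r;
    cur = best;
    tr_rss.push_back(cur);
  }

  return Rcpp::List::create(
    Rcpp::Named("idx") = idx,
    Rcpp::Named("rss") = cur,
    Rcpp::Named("sweep") = tr_sweep,
    Rcpp::Named("out") = tr_out,
    Rcpp::Named("in") = tr_in,
    Rcpp::Named("rss_after") = tr_rss);
}

// Alternating continuous archetype fit from a starting Z0.
// Each accepted iteration: A <- optimal simplex weights; Z_ls <- unconstrained
// LS update; each archetype projected back into the convex hull of X via a
// simplex-LS beta row; the candidate (Z, A) is accepted only if it lowers RSS,
// so the recorded RSS path is non-increasing by construction.
// [[Rcpp::export]]
Rcpp::List cpp_fit_archetypes_run(const arma::mat& X, const arma::mat& Z0,
                                  const double tol, const int max_iter) {
  const uword n = X.n_rows, m = X.n_cols, k = Z0.n_rows;

  mat augX(m + 1, n);           // basis = all data rows (for beta updates)
  augX.rows(0, m - 1) = X.t();

  // hull-feasible start: beta rows for Z0, then Z = B X
  mat B(k, n);
  for (uword j = 0; j < k; ++j) B.row(j) = simplex_weights_aug(augX, Z0.row(j)).t();
  mat Z = B * X;

  Rcpp::List al = cpp_alphas(X, Z);
  mat A = Rcpp::as<mat>(al["A"]);
  double cur = accu(Rcpp::as<vec>(al["resid"]));

  std::vector<double> path;
  path.push_back(cur);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // unconstrained archetype update given A (ridge guards singular A'A)
    mat G = A.t() * A;
    G.diag() += 1e-10;
    mat Zls;
    if (!solve(Zls, G, A.t() * X,
               solve_opts::likely_sympd + solve_opts::no_approx)) {
      Zls = pinv(G) * (A.t() * X);
    }

    mat Bc(k, n);
    for (uword j = 0; j < k; ++j) Bc.row(j) = simplex_weights_aug(augX, Zls.row(j)).t();
    mat Zc = Bc * X;

    Rcpp::List alc = cpp_alphas(X, Zc);
    mat Ac = Rcpp::as<mat>(alc["A"]);
    double cand = accu(Rcpp::as<vec>(alc["resid"]));

    if (cand >= cur) { converged = true; break; }  // hull projection stalled
    double rel = (cur - cand) / std::max(cur, 1e-300);
    Z = Zc; A = Ac; B = Bc; cur = cand;
    path.push_back(cur);
    if (rel < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("Z") = Z,
    Rcpp::Named("A") = A,
    Rcpp::Named("B") = B,
    Rcpp::Named("rss") = cur,
    Rcpp::Named("rss_path") = path,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
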