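// Dense bounded-variable two-phase primal simplex (maximization form).
//
// Solves  max c'x  s.t.  A x = b,  lb <= x <= ub  with finite or
// infinite bounds. Phase 1 drives signed artificial variables to zero;
// phase 2 optimizes with the artificials pinned at zero, which copes
// with redundant rows (conservation relations in stoichiometric
// matrices) without an explicit drive-out step. The basis inverse is
// maintained by eta updates with periodic refactorization; Dantzig
// pricing switches to Bland's rule after a stall so degenerate
// problems terminate. At claimed optimality the basis is refactorized
// and primal feasibility re-verified: if eta-update drift has let a
// basic variable slip past its bound, the solve is restarted in a
// conservative mode (Bland from the first iteration, tight
// refactorization) whose pivots are chosen from clean values.
// Returns row prices (lambda) and reduced costs for the
// strong-duality audit upstream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct SimplexResult {
  int status; // 0 optimal, 1 infeasible, 2 unbounded, 3 drifted
  vec x;
  double obj;
  rowvec lambda;
  vec reduced;
  int iterations;
};

SimplexResult run_simplex(const mat& A, const vec& b, const vec& c,
                          const vec& lb, const vec& ub, double tol,
                          int maxit, bool conservative) {
  const uword m = A.n_rows, n = A.n_cols, N = n + m;
  SimplexResult res;
  res.status = 1;
  res.obj = 0.0;
  res.iterations = 0;

  vec lab(N), uab(N);
  lab.head(n) = lb;
  uab.head(n) = ub;
  lab.tail(m).zeros();
  uab.tail(m).fill(datum::inf);

  vec val(N, fill::zeros);
  ivec stat(N, fill::zeros); // 0 basic, 1 at lb, 2 at ub, 3 free at 0
  for (uword j = 0; j < n; ++j) {
    const bool lf = std::isfinite(lb[j]), uf = std::isfinite(ub[j]);
    if (lf && (!uf || std::abs(lb[j]) <= std::abs(ub[j]))) {
      val[j] = lb[j]; stat[j] = 1;
    } else if (uf) {
      val[j] = ub[j]; stat[j] = 2;
    } else {
      val[j] = 0.0; stat[j] = 3;
    }
  }

  const vec r = b - A * val.head(n);
  vec asgn(m);
  for (uword i = 0; i < m; ++i) asgn[i] = (r[i] >= 0.0) ? 1.0 : -1.0;

  mat Aaug(m, N);
  Aaug.cols(0, n - 1) = A;
  Aaug.cols(n, N - 1) = diagmat(asgn);

  uvec basis = regspace<uvec>(n, N - 1);
  for (uword i = 0; i < m; ++i) { val[n + i] = std::abs(r[i]); stat[n + i] = 0; }
  mat Binv = diagmat(1.0 / asgn);

  int phase = 1;
  vec cph(N, fill::zeros);
  cph.tail(m).fill(-1.0);
  vec cint(N, fill::zeros);
  cint.head(n) = c;

  const double bscale = std::max(1.0, (m > 0) ? abs(b).max() : 1.0);
  const int bland_after =
      conservative ? 0 : 2000 + 40 * static_cast<int>(m + n);
  const int refresh_every = conservative ? 10 : 30;
  const double pivtol = 1e-10;
  int it = 0, refresh = 0, final_checks = 0;

  while (true) {
    if (++it > maxit) Rcpp::stop("simplex iteration limit reached");
    vec xB = val(basis);
    rowvec y = cph(basis).t() * Binv;
    vec d = cph - (y * Aaug).t();
    d(basis).zeros();

    int q = -1;
    double bestd = 0.0;
    const bool bland = it > bland_after;
    for (uword j = 0; j < N; ++j) {
      if (stat[j] == 0) continue;
      const double dj = d[j];
      const bool can = ((stat[j] == 1 || stat[j] == 3) && dj > tol) ||
                       (stat[j] == 2 && dj < -tol);
      if (!can) continue;
      if (bland) { q = static_cast<int>(j); break; }
      if (std::abs(dj) > bestd) { bestd = std::abs(dj); q = static_cast<int>(j); }
    }

    if (q < 0) { // current phase looks optimal: refactor and verify
      mat Bi;
      if (inv(Bi, Aaug.cols(basis))) {
        Binv = Bi;
        vec rhs = b;
        for (uword j = 0; j < N; ++j)
          if (stat[j] != 0 && val[j] != 0.0) rhs -= Aaug.col(j) * val[j];
        val(basis) = Binv * rhs;
      }
      if (phase == 2) {
        // split bound violations of basics into structural drift and
        // residual artificials (the latter signal leaked infeasibility:
        // in phase 2 the artificials are pinned to zero)
        double viol_s = 0.0, viol_a = 0.0;
        for (uword i = 0; i < m; ++i) {
          const uword j = basis[i];
          double v = 0.0;
          if (std::isfinite(lab[j])) v = std::max(v, lab[j] - val[j]);
          if (std::isfinite(uab[j])) v = std::max(v, val[j] - uab[j]);
          if (j < n) viol_s = std::max(viol_s, v);
          else viol_a = std::max(viol_a, v);
        }
        if (viol_s > 1e-7 || viol_a > 1e-7) {
          if (!conservative) { res.status = 3; return res; }
          if (viol_a > 1e-7) { res.status = 1; return res; }
          if (viol_s > 1e-5) { res.status = 3; return res; }
          // tolerance-level noise on an ill-conditioned basis: snap
          // into the box and accept
          for (uword i = 0; i < m; ++i) {
            const uword j = basis[i];
            if (std::isfinite(lab[j]) && val[j] < lab[j]) val[j] = lab[j];
            if (std::isfinite(uab[j]) && val[j] > uab[j]) val[j] = uab[j];
          }
        }
      }
      // pricing may change on the clean factorization; re-enter (bounded)
      if (final_checks++ < 4) {
        vec d2 = cph - (cph(basis).t() * Binv * Aaug).t();
        d2(basis).zeros();
        bool more = false;
        for (uword j = 0; j < N && !more; ++j) {
          if (stat[j] == 0) continue;
          more = ((stat[j] == 1 || stat[j] == 3) && d2[j] > tol) ||
                 (stat[j] == 2 && d2[j] < -tol);
        }
        if (more) continue;
      }
      if (phase == 1) {
        const double p1 = dot(cph(basis), val(basis));
        if (p1 < -1e-7 * bscale) { res.status = 1; return res; }
        for (uword j = n; j < N; ++j) {
          lab[j] = 0.0; uab[j] = 0.0;
          if (stat[j] != 0) val[j] = 0.0;
        }
        phase = 2;
        cph = cint;
        final_checks = 0;
        continue;
      }
      res.status = 0;
      res.x = val.head(n);
      res.obj = dot(c, val.head(n));
      res.lambda = cph(basis).t() * Binv;
      const vec redfull = cph - (res.lambda * Aaug).t();
      res.reduced = redfull.head(n);
      res.iterations = it;
      return res;
    }

    const double tdir = (stat[q] == 2) ? -1.0 : 1.0;
    vec w = Binv * Aaug.col(q);

    double theta = (std::isfinite(lab[q]) && std::isfinite(uab[q]))
                       ? (uab[q] - lab[q]) : datum::inf;
    int leave = -1, lhit = 0;
    for (uword i = 0; i < m; ++i) {
      const double tw = tdir * w[i];
      if (tw > pivtol) {
        const double li = lab[basis[i]];
        if (std::isfinite(li)) {
          const double th = (xB[i] - li) / tw;
          if (th < theta - 1e-12 ||
              (th < theta + 1e-12 &&
               (leave < 0 || basis[i] < basis[leave]))) {
            theta = th; leave = static_cast<int>(i); lhit = 1;
          }
        }
      } else if (tw < -pivtol) {
        const double ui = uab[basis[i]];
        if (std::isfinite(ui)) {
          const double th = (ui - xB[i]) / (-tw);
          if (th < theta - 1e-12 ||
              (th < theta + 1e-12 &&
               (leave < 0 || basis[i] < basis[leave]))) {
            theta = th; leave = static_cast<int>(i); lhit = 2;
          }
        }
      }
    }

    if (!std::isfinite(theta)) {
      if (phase == 1) Rcpp::stop("phase-1 subproblem unbounded (internal error)");
      res.status = 2;
      return res;
    }
    if (theta < 0.0) theta = 0.0;

    val(basis) = xB - tdir * theta * w;
    val[q] += tdir * theta;

    if (leave < 0) {
      stat[q] = (stat[q] == 1) ? 2 : 1; // bound flip
    } else {
      const uword out = basis[leave];
      stat[out] = lhit;
      val[out] = (lhit == 1) ? lab[out] : uab[out];
      stat[q] = 0;
      basis[leave] = q;
      const double wr = w[leave];
      if (std::abs(wr) < 1e-11) {
        Binv = inv(Aaug.cols(basis));
      } else {
        const rowvec Br = Binv.row(leave) / wr;
        Binv -= w * Br;
        Binv.row(leave) = Br;
      }
      if (++refresh >= refresh_every) {
        refresh = 0;
        mat Bi;
        if (inv(Bi, Aaug.cols(basis))) {
          Binv = Bi;
          vec rhs = b;
          for (uword j = 0; j < N; ++j)
            if (stat[j] != 0 && val[j] != 0.0) rhs -= Aaug.col(j) * val[j];
          val(basis) = Binv * rhs;
        }
      }
    }
  }
}

} // namespace

// status: 0 optimal, 1 infeasible, 2 unbounded
// [[Rcpp::export(name = ".simplex_core")]]
Rcpp::List simplex_core(const arma::mat& A, const arma::vec& b,
                        const arma::vec& c, const arma::vec& lb,
                        const arma::vec& ub, double tol, int maxit) {
  SimplexResult res = run_simplex(A, b, c, lb, ub, tol, maxit, false);
  if (res.status == 3) // drift detected: redo with conservative pivoting
    res = run_simplex(A, b, c, lb, ub, tol, maxit, true);
  if (res.status == 3)
    Rcpp::stop("simplex could not reach a numerically clean optimum");
  if (res.status != 0)
    return Rcpp::List::create(Rcpp::Named("status") = res.status);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0,
      Rcpp::Named("x") = Rcpp::NumericVector(res.x.begin(), res.x.end()),
      Rcpp::Named("obj") = res.obj,
      Rcpp::Named("lambda") =
          Rcpp::NumericVector(res.lambda.begin(), res.lambda.end()),
      Rcpp::Named("reduced") =
          Rcpp::NumericVector(res.reduced.begin(), res.reduced.end()),
      Rcpp::Named("iterations") = res.iterations);
}
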