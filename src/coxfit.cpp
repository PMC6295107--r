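#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Breslow-ties Cox partial log-likelihood with optional gradient/Hessian.
// Rows must be pre-sorted by time in increasing order; status is 0/1.
// The risk-set sums are accumulated in a single backward pass; tied event
// times share one risk set (Breslow convention).
static void cox_derivs(const arma::mat& X, const arma::vec& time,
                       const arma::ivec& status, const arma::vec& beta,
                       bool want_deriv,
                       double& ll, arma::vec& grad, arma::mat& hess)
{
    const int n = X.n_rows;
    const int p = X.n_cols;
    arma::vec eta = X * beta;
    ll = 0.0;
    if (want_deriv) {
        grad.zeros(p);
        hess.zeros(p, p);
    }
    double r0 = 0.0;
    arma::vec r1(p, arma::fill::zeros);
    arma::mat r2(p, p, arma::fill::zeros);
    int i = n - 1;
    while (i >= 0) {
        int j = i;
        while (j >= 0 && time(j) == time(i)) --j;
        for (int k = j + 1; k <= i; ++k) {
            double w = std::exp(eta(k));
            r0 += w;
            if (want_deriv) {
                for (int a = 0; a < p; ++a) {
                    const double xa = X(k, a);
                    r1(a) += w * xa;
                    for (int b = 0; b <= a; ++b)
                        r2(a, b) += w * xa * X(k, b);
                }
            }
        }
        int d = 0;
        for (int k = j + 1; k <= i; ++k) {
            if (status(k) == 1) {
                ++d;
                ll += eta(k);
                if (want_deriv)
                    for (int a = 0; a < p; ++a) grad(a) += X(k, a);
            }
        }
        if (d > 0) {
            ll -= d * std::log(r0);
            if (want_deriv) {
                for (int a = 0; a < p; ++a) {
                    const double ma = r1(a) / r0;
                    grad(a) -= d * ma;
                    for (int b = 0; b <= a; ++b)
                        hess(a, b) -= d * (r2(a, b) / r0 -
                                           ma * (r1(b) / r0));
                }
            }
        }
        i = j;
    }
    if (want_deriv)
        for (int a = 0; a < p; ++a)
            for (int b = a + 1; b < p; ++b) {
                hess(a, b) = hess(b, a);
                r2(a, b) = r2(b, a);
            }
}

// Newton-Raphson with step halving. Returns true when the score converged
// below tol_score; monotone-likelihood (separation) cases hit the beta cap
// and come back with converged = false and capped coefficients.
static bool cox_newton(const arma::mat& X, const arma::vec& time,
                       const arma::ivec& status,
                       int maxit, double tol_score, double tol_ll,
                       double beta_cap,
                       arma::vec& beta, arma::mat& cov, double& ll, int& iter)
{
    const int p = X.n_cols;
    beta.zeros(p);
    arma::vec grad(p);
    arma::mat hess(p, p);
    cox_derivs(X, time, status, beta, true, ll, grad, hess);
    bool conv = false;
    for (iter = 0; iter < maxit; ++iter) {
        if (arma::abs(grad).max() < tol_score) {
            conv = true;
            break;
        }
        arma::vec step;
        bool ok = arma::solve(step, -hess, grad,
                              arma::solve_opts::no_approx);
        if (!ok) break;
        double f = 1.0;
        arma::vec bnew = beta + step;
        double ll_new = -arma::datum::inf;
        arma::vec gdum;
        arma::mat hdum;
        for (int h = 0; h < 30; ++h) {
            cox_derivs(X, time, status, bnew, false, ll_new, gdum, hdum);
            if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
            f *= 0.5;
            bnew = beta + f * step;
        }
        double delta = std::abs(ll_new - ll);
        beta = bnew;
        cox_derivs(X, time, status, beta, true, ll, grad, hess);
        if (arma::abs(beta).max() > beta_cap) {
            beta = arma::clamp(beta, -beta_cap, beta_cap);
            cox_derivs(X, time, status, beta, true, ll, grad, hess);
            conv = false;
            break;
        }
        if (delta < tol_ll * (std::abs(ll) + 1.0)) {
            conv = arma::abs(grad).max() < tol_score * 1e4;
            break;
        }
    }
    if (arma::abs(grad).max() < tol_score) conv = true;
    bool okc = arma::inv_sympd(cov, -hess);
    if (!okc) okc = arma::inv(cov, -hess);
    if (!okc) cov = arma::mat(p, p, arma::fill::value(NA_REAL));
    return conv;
}

// [[Rcpp::export]]
List cox_newton_cpp(const arma::mat& X, const arma::vec& time,
                    const IntegerVector& status,
                    int maxit = 50, double tol_score = 1e-8,
                    double tol_ll = 1e-10, double beta_cap = 15.0)
{
    arma::ivec st(status.size());
    for (int i = 0; i < status.size(); ++i) st(i) = status[i];
    arma::vec beta;
    arma::mat cov;
    double ll = NA_REAL;
    int iter = 0;
    bool conv = cox_newton(X, time, st, maxit, tol_score, tol_ll, beta_cap,
                           beta, cov, ll, iter);
    return List::create(_["coefficients"] = beta,
                        _["covariance"] = cov,
                        _["loglik"] = ll,
                        _["converged"] = conv,
                        _["iter"] = iter);
}

// Breslow baseline cumulative hazard evaluated at each subject's own
// observed time, in the original subject order. ord is the 0-based
// ascending-time permutation (precomputed in R).
// [[Rcpp::export]]
arma::vec breslow_cumhaz_at_cpp(const arma::vec& time,
                                const IntegerVector& status,
                                const arma::vec& eta,
                                const IntegerVector& ord)
{
    const int n = time.n_elem;
    arma::vec denom(n);
    double acc = 0.0;
    for (int k = n - 1; k >= 0; --k) {
        acc += std::exp(eta(ord[k]));
        denom(k) = acc;
    }
    // within a tied block every position shares the block-head denominator
    arma::vec cum(n);
    double lam = 0.0;
    int i = 0;
    while (i < n) {
        int j = i;
        const double t0 = time(ord[i]);
        while (j < n && time(ord[j]) == t0) ++j;
        int d = 0;
        for (int k = i; k < j; ++k)
            if (status[ord[k]] == 1) ++d;
        if (d > 0) lam += d / denom(i);
        for (int k = i; k < j; ++k) cum(k) = lam;
        i = j;
    }
    arma::vec out(n);
    for (int k = 0; k < n; ++k) out(ord[k]) = cum(k);
    return out;
}

// High-risk indicator matrix: for each combination (column of cellIdx,
// 1-based cell codes, NA_INTEGER = missing genotype) accumulate the
// residual sum per cell and emit S = 1{cell sum > 0} per subject.
// [[Rcpp::export]]
NumericMatrix indicator_matrix_cpp(const IntegerMatrix& cellIdx,
                                   const NumericVector& M, int ncell)
{
    const int n = cellIdx.nrow();
    const int C = cellIdx.ncol();
    NumericMatrix S(n, C);
    std::vector<double> sums(ncell);
    for (int j = 0; j < C; ++j) {
        std::fill(sums.begin(), sums.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            const int c = cellIdx(i, j);
            if (c != NA_INTEGER) sums[c - 1] += M[i];
        }
        for (int i = 0; i < n; ++i) {
            const int c = cellIdx(i, j);
            S(i, j) = (c == NA_INTEGER) ? NA_REAL
                                        : (sums[c - 1] > 0 ? 1.0 : 0.0);
        }
    }
    return S;
}

// Wald scan: for each column s of S fit a Cox model with design [s, Z] and
// return beta, se and W = (beta/se)^2 for the s term. Degenerate (constant)
// S columns must be filtered out by the caller.
// [[Rcpp::export]]
NumericMatrix cox_wald_scan_cpp(const arma::mat& S, const arma::mat& Z,
                                const arma::vec& time,
                                const IntegerVector& status,
                                int maxit = 50, double tol_score = 1e-8,
                                double tol_ll = 1e-10, double beta_cap = 15.0)
{
    const int n = S.n_rows;
    const int nscan = S.n_cols;
    const int pz = Z.n_cols;
    arma::ivec st(status.size());
    for (int i = 0; i < status.size(); ++i) st(i) = status[i];
    arma::mat X(n, 1 + pz);
    if (pz > 0) X.cols(1, pz) = Z;
    NumericMatrix out(4, nscan);
    rownames(out) = CharacterVector::create("beta", "se", "W", "converged");
    for (int j = 0; j < nscan; ++j) {
        X.col(0) = S.col(j);
        arma::vec beta;
        arma::mat cov;
        double ll;
        int iter;
        bool conv = cox_newton(X, time, st, maxit, tol_score, tol_ll,
                               beta_cap, beta, cov, ll, iter);
        double se = std::sqrt(cov(0, 0));
        out(0, j) = beta(0);
        out(1, j) = se;
        out(2, j) = (se > 0 && std::isfinite(se))
                        ? (beta(0) / se) * (beta(0) / se)
                        : NA_REAL;
        out(3, j) = conv ? 1.0 : 0.0;
    }
    return out;
}
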