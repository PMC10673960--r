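#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iteratively reweighted least squares for a Bernoulli-logistic fit with a
// small fixed design (k <= 3 columns). Fitted probabilities are clamped to
// [1e-12, 1-1e-12] so the log-likelihood stays bounded under complete
// separation; iteration cap 100.

static const double P_EPS = 1e-12;
static const int MAX_IT = 100;

// solve k x k system in place (Gaussian elimination, partial pivoting);
// returns false if numerically singular
static bool solve_small(double A[3][3], double b[3], double x[3], int k) {
  int piv[3] = {0, 1, 2};
  for (int c = 0; c < k; ++c) {
    int best = c;
    for (int r = c + 1; r < k; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    double d = A[piv[c]][c];
    if (std::fabs(d) < 1e-12) return false;
    for (int r = c + 1; r < k; ++r) {
      double f = A[piv[r]][c] / d;
      for (int cc = c; cc < k; ++cc) A[piv[r]][cc] -= f * A[piv[c]][cc];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double s = b[piv[c]];
    for (int cc = c + 1; cc < k; ++cc) s -= A[piv[c]][cc] * x[cc];
    x[c] = s / A[piv[c]][c];
  }
  return true;
}

// log-likelihood-maximising logistic fit; X is n x k (column-major),
// returns maximised log-likelihood, coefficients in beta
static double irls(const double* X, const double* y, int n, int k,
                   double* beta) {
  for (int j = 0; j < k; ++j) beta[j] = 0.0;
  double ll_old = -1e300;
  std::vector<double> eta(n), p(n);
  for (int it = 0; it < MAX_IT; ++it) {
    double A[3][3] = {{0}}, bvec[3] = {0}, xsol[3] = {0};
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < k; ++j) e += X[j * n + i] * beta[j];
      eta[i] = e;
      double pi = 1.0 / (1.0 + std::exp(-e));
      if (pi < P_EPS) pi = P_EPS;
      if (pi > 1.0 - P_EPS) pi = 1.0 - P_EPS;
      p[i] = pi;
      ll += y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi);
    }
    if (std::fabs(ll - ll_old) < 1e-10) return ll;
    ll_old = ll;
    for (int i = 0; i < n; ++i) {
      double w = p[i] * (1.0 - p[i]);
      if (w < 1e-10) w = 1e-10;
      double z = eta[i] + (y[i] - p[i]) / w;
      for (int j = 0; j < k; ++j) {
        double xij = X[j * n + i];
        bvec[j] += w * xij * z;
        for (int l = j; l < k; ++l) A[j][l] += w * xij * X[l * n + i];
      }
    }
    for (int j = 0; j < k; ++j)
      for (int l = 0; l < j; ++l) A[j][l] = A[l][j];
    // tiny ridge keeps collinear designs (e.g. a constant covariate equal
    // to the intercept) solvable without changing regular fits
    for (int j = 0; j < k; ++j) A[j][j] += 1e-10;
    if (!solve_small(A, bvec, xsol, k)) return ll;
    for (int j = 0; j < k; ++j) beta[j] = xsol[j];
  }
  return ll_old;
}

static double null_ll(const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += y[i];
  double p = s / n;
  if (p <= 0.0 || p >= 1.0) return 0.0;
  return s * std::log(p) + (n - s) * std::log(1.0 - p);
}

// lod at one position: covariates intercept, pAB, pBB
static double lod_one(const double* pab, const double* pbb, const double* y,
                      double ll0, int n, std::vector<double>& X) {
  for (int i = 0; i < n; ++i) {
    X[i] = 1.0;
    X[n + i] = pab[i];
    X[2 * n + i] = pbb[i];
  }
  double beta[3];
  double ll1 = irls(X.data(), y, n, 3, beta);
  double lod = (ll1 - ll0) / std::log(10.0);
  return lod > 0.0 ? lod : 0.0;
}

// [[Rcpp::export]]
NumericVector scan_binary_cpp(NumericMatrix pAB, NumericMatrix pBB,
                              NumericVector y) {
  int n = pAB.nrow(), P = pAB.ncol();
  NumericVector lod(P);
  double ll0 = null_ll(y.begin(), n);
  std::vector<double> X(3 * n);
  for (int j = 0; j < P; ++j)
    lod[j] = lod_one(&pAB(0, j), &pBB(0, j), y.begin(), ll0, n, X);
  return lod;
}

// genome-wide maximum lod per permuted phenotype column
// [[Rcpp::export]]
NumericVector perm_max_lod_cpp(NumericMatrix pAB, NumericMatrix pBB,
                               NumericMatrix Yperm) {
  int n = pAB.nrow(), P = pAB.ncol(), K = Yperm.ncol();
  NumericVector out(K);
  std::vector<double> X(3 * n);
  for (int k = 0; k < K; ++k) {
    const double* y = &Yperm(0, k);
    double ll0 = null_ll(y, n);
    double mx = 0.0;
    for (int j = 0; j < P; ++j) {
      double l = lod_one(&pAB(0, j), &pBB(0, j), y, ll0, n, X);
      if (l > mx) mx = l;
    }
    out[k] = mx;
  }
  return out;
}

// per-position genotype-class log-odds: no-intercept fit on pAA, pAB, pBB
// [[Rcpp::export]]
NumericMatrix effects_cpp(NumericMatrix pAA, NumericMatrix pAB,
                          NumericMatrix pBB, NumericVector y) {
  int n = pAA.nrow(), P = pAA.ncol();
  NumericMatrix out(P, 3);
  std::vector<double> X(3 * n);
  double beta[3];
  for (int j = 0; j < P; ++j) {
    for (int i = 0; i < n; ++i) {
      X[i] = pAA(i, j);
      X[n + i] = pAB(i, j);
      X[2 * n + i] = pBB(i, j);
    }
    irls(X.data(), y.begin(), n, 3, beta);
    for (int c = 0; c < 3; ++c) out(j, c) = beta[c];
  }
  return out;
}
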