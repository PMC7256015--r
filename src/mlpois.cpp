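// Per-ray Poisson maximum-likelihood basis-material decomposition.
//
// Model: lambda_b(A) = sum_e W[e,b] * exp(-sum_m MU[e,m] * A[m]), with W the
// flux-scaled spectrum-times-bin-response weights (so blank_b = sum_e W[e,b])
// and MU the mass attenuation matrix (cm^2/g); A is in g/cm^2.
// ell(A) = sum_b [ y_b log lambda_b - lambda_b ]  (y log lambda dropped at y=0).
//
// Maximizer: Newton iterations with exact Hessian and step halving,
// initialized from the caller-supplied (weighted-least-squares) estimate;
// Fisher-scoring fallback when the Newton direction is not an ascent
// direction. Unconstrained: negative A allowed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAXM = 4;

// solve S x = b for small symmetric positive-definite S (M<=4), Cholesky;
// returns false if not PD
static bool chol_solve(double S[MAXM][MAXM], double b[MAXM], double x[MAXM], int M) {
  double L[MAXM][MAXM] = {{0}};
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = S[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 1e-300) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  double z[MAXM];
  for (int i = 0; i < M; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * z[k];
    z[i] = s / L[i][i];
  }
  for (int i = M - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < M; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

struct RayWork {
  std::vector<double> u;      // exp(-MU A) per energy
  std::vector<double> lam, G, K;
};

// evaluate lambda, log-likelihood; optionally G_bm and K_bmk sums
static double eval_ray(const NumericMatrix& W, const NumericMatrix& MU,
                       const double* A, const double* y, int E, int B, int M,
                       RayWork& wk, bool derivs) {
  for (int e = 0; e < E; ++e) {
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += MU(e, m) * A[m];
    wk.u[e] = std::exp(-s);
  }
  std::fill(wk.lam.begin(), wk.lam.end(), 0.0);
  if (derivs) {
    std::fill(wk.G.begin(), wk.G.end(), 0.0);
    std::fill(wk.K.begin(), wk.K.end(), 0.0);
  }
  for (int b = 0; b < B; ++b) {
    for (int e = 0; e < E; ++e) {
      const double we = W(e, b) * wk.u[e];
      if (we == 0.0) continue;
      wk.lam[b] += we;
      if (derivs) {
        for (int m = 0; m < M; ++m) {
          const double wm = we * MU(e, m);
          wk.G[b * M + m] += wm;
          for (int k = m; k < M; ++k)
            wk.K[(b * M + m) * M + k] += wm * MU(e, k);
        }
      }
    }
  }
  double ell = 0.0;
  for (int b = 0; b < B; ++b) {
    double lb = wk.lam[b];
    if (lb < 1e-300) lb = 1e-300;
    if (y[b] > 0) ell += y[b] * std::log(lb);
    ell -= lb;
  }
  return ell;
}

// [[Rcpp::export]]
List cpp_ml_decompose(const NumericMatrix& Y,      // rays x bins
                      const NumericMatrix& W,      // E x bins (flux-scaled)
                      const NumericMatrix& MU,     // E x materials
                      const NumericMatrix& Ainit,  // rays x materials
                      const int max_iter,
                      const double grad_tol_scale) {
  const int R = Y.nrow(), B = Y.ncol(), E = W.nrow(), M = MU.ncol();
  if (M > MAXM) stop("at most 4 basis materials supported");
  if (B < M) stop("need at least as many bins as basis materials");
  NumericMatrix A(R, M);
  LogicalVector conv(R);
  IntegerVector niter(R);
  RayWork wk;
  wk.u.resize(E); wk.lam.resize(B); wk.G.resize(B * M); wk.K.resize(B * M * M);

  for (int r = 0; r < R; ++r) {
    double y[16], a[MAXM];
    double ytot = 0.0;
    for (int b = 0; b < B; ++b) { y[b] = Y(r, b); ytot += y[b]; }
    if (ytot <= 0.0) {            // all-zero counts: flag, report A = 0
      for (int m = 0; m < M; ++m) A(r, m) = 0.0;
      conv[r] = false; niter[r] = 0;
      continue;
    }
    for (int m = 0; m < M; ++m) a[m] = Ainit(r, m);
    const double tol = grad_tol_scale * (1.0 + ytot);
    double ell = eval_ray(W, MU, a, y, E, B, M, wk, true);
    bool ok = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      // gradient and Hessian of ell
      double g[MAXM] = {0}, H[MAXM][MAXM] = {{0}}, FI[MAXM][MAXM] = {{0}};
      for (int b = 0; b < B; ++b) {
        const double lb = std::max(wk.lam[b], 1e-300);
        const double resid = 1.0 - y[b] / lb;        // dl/dA_m = sum_b resid*G
        for (int m = 0; m < M; ++m) {
          const double Gbm = wk.G[b * M + m];
          g[m] += resid * Gbm;
          for (int k = m; k < M; ++k) {
            const double Gbk = wk.G[b * M + k];
            const double Kmk = wk.K[(b * M + m) * M + k];
            H[m][k] += -y[b] * Gbm * Gbk / (lb * lb) + (y[b] / lb - 1.0) * Kmk;
            FI[m][k] += Gbm * Gbk / lb;
          }
        }
      }
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < m; ++k) { H[m][k] = H[k][m]; FI[m][k] = FI[k][m]; }
      double gmax = 0.0;
      for (int m = 0; m < M; ++m) gmax = std::max(gmax, std::fabs(g[m]));
      if (gmax < tol) { ok = true; break; }
      // Newton direction on -H (expected negative definite); Fisher fallback
      double negH[MAXM][MAXM], d[MAXM];
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < M; ++k) negH[m][k] = -H[m][k];
      bool have_dir = chol_solve(negH, g, d, M);
      if (!have_dir) have_dir = chol_solve(FI, g, d, M);
      if (!have_dir) break;
      // negligible step: already at the optimum to machine precision
      double dmax = 0.0, amax = 0.0;
      for (int m = 0; m < M; ++m) {
        dmax = std::max(dmax, std::fabs(d[m]));
        amax = std::max(amax, std::fabs(a[m]));
      }
      if (dmax < 1e-12 * (1.0 + amax)) { ok = true; break; }
      // step halving on the log-likelihood (tolerance relative to its scale)
      const double ell_tol = 1e-10 * (1.0 + std::fabs(ell));
      double alpha = 1.0, ell_new = -HUGE_VAL;
      double atrial[MAXM];
      bool improved = false;
      for (int h = 0; h < 30; ++h) {
        for (int m = 0; m < M; ++m) atrial[m] = a[m] + alpha * d[m];
        ell_new = eval_ray(W, MU, atrial, y, E, B, M, wk, false);
        if (ell_new >= ell - ell_tol) { improved = true; break; }
        alpha *= 0.5;
      }
      if (!improved) { ok = dmax < 1e-6 * (1.0 + amax); break; }
      for (int m = 0; m < M; ++m) a[m] = atrial[m];
      ell = eval_ray(W, MU, a, y, E, B, M, wk, true);  // refresh derivatives
    }
    for (int m = 0; m < M; ++m) A(r, m) = a[m];
    conv[r] = ok;
    niter[r] = it;
  }
  return List::create(_["A"] = A, _["converged"] = conv, _["niter"] = niter);
}

// Weighted least squares on log-transmission with per-bin effective
// coefficients: minimize sum_b w_b (p_b - sum_m Meff[b,m] A_m)^2,
// p_b = -log(max(y_b, clamp)/blank_b), w_b = max(y_b, 1).
// [[Rcpp::export]]
NumericMatrix cpp_wls_decompose(const NumericMatrix& Y,
                                const NumericVector& blank,
                                const NumericMatrix& Meff,  // bins x materials
                                const double clamp) {
  const int R = Y.nrow(), B = Y.ncol(), M = Meff.ncol();
  if (M > MAXM) stop("at most 4 basis materials supported");
  NumericMatrix A(R, M);
  for (int r = 0; r < R; ++r) {
    double S[MAXM][MAXM] = {{0}}, b[MAXM] = {0}, x[MAXM] = {0};
    double ytot = 0.0;
    for (int bb = 0; bb < B; ++bb) ytot += Y(r, bb);
    if (ytot > 0.0) {
      for (int bb = 0; bb < B; ++bb) {
        const double yb = Y(r, bb);
        const double w = yb > 1.0 ? yb : 1.0;
        const double p = -std::log(std::max(yb, clamp) / blank[bb]);
        for (int m = 0; m < M; ++m) {
          b[m] += w * p * Meff(bb, m);
          for (int k = m; k < M; ++k)
            S[m][k] += w * Meff(bb, m) * Meff(bb, k);
        }
      }
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < m; ++k) S[m][k] = S[k][m];
      if (!chol_solve(S, b, x, M))
        for (int m = 0; m < M; ++m) x[m] = 0.0;
    }
    for (int m = 0; m < M; ++m) A(r, m) = x[m];
  }
  return A;
}
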