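#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients must be normalised so
// that a[0] == 1 (done on the R side). Single forward pass, zero initial
// state, length preserved.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  int n = x.size();
  std::vector<double> z(nz, 0.0);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz; ++j) {
      double znext = (j + 1 < nz) ? z[j + 1] : 0.0;
      z[j] = bb[j + 1] * xi + znext - aa[j + 1] * yi;
    }
    y[i] = yi;
  }
  return y;
}

// ---------------------------------------------------------------------------
// Sequential minimal optimisation (Platt-style) for a binary soft-margin SVM
// with RBF kernel K(u,v) = exp(-||u-v||^2 / (2 sigma^2)).
// Internally the Platt convention u(x) = sum_i alpha_i y_i K(x_i, x) - b is
// used; the returned threshold is negated so callers can score rows as
// sum_i alpha_i y_i K(x_i, x) + b.
// Deterministic: working-set sweeps use fixed index order.
// ---------------------------------------------------------------------------

namespace {

struct SmoState {
  const arma::mat &K;
  const arma::vec &y;
  arma::vec alpha;
  arma::vec f;  // current decision value for every training point
  double b;
  double C, tol, eps;

  SmoState(const arma::mat &K_, const arma::vec &y_, double C_, double tol_)
      : K(K_), y(y_), alpha(y_.n_elem, arma::fill::zeros),
        f(y_.n_elem, arma::fill::zeros), b(0.0), C(C_), tol(tol_),
        eps(1e-8) {}

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = f[i1] - y1, E2 = f[i2] - y2;
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (H - L < eps) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 1e-12) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // objective at the two clip ends
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double psiL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double psiH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (psiL < psiH - 1e-12) a2new = L;
      else if (psiL > psiH + 1e-12) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < 1e-10 * (a2new + a2 + 1e-10)) return false;
    double a1new = a1 + s * (a2 - a2new);
    // threshold update (keep KKT for the two changed points)
    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > 0 && a1new < C) bnew = b1;
    else if (a2new > 0 && a2new < C) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    double db = bnew - b;
    f += y1 * (a1new - a1) * K.col(i1) + y2 * (a2new - a2) * K.col(i2) - db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2];
    double E2 = f[i2] - y2;
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximise |E1 - E2| over non-bound points
      int best = -1;
      double bestgap = 0.0;
      for (arma::uword i = 0; i < alpha.n_elem; ++i) {
        if (alpha[i] > 0 && alpha[i] < C) {
          double gap = std::fabs((f[i] - y[i]) - E2);
          if (gap > bestgap) { bestgap = gap; best = (int)i; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return true;
      // heuristic 2: sweep non-bound, then all (fixed order: deterministic)
      for (arma::uword i = 0; i < alpha.n_elem; ++i)
        if (alpha[i] > 0 && alpha[i] < C && take_step((int)i, i2)) return true;
      for (arma::uword i = 0; i < alpha.n_elem; ++i)
        if (take_step((int)i, i2)) return true;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_svm_smo(const arma::mat &K, const arma::vec &y, double C,
                 double tol = 1e-3, int max_passes = 2000) {
  SmoState st(K, y, C, tol);
  int n = (int)y.n_elem;
  bool examine_all = true;
  int num_changed = 0;
  int pass = 0;
  while ((num_changed > 0 || examine_all) && pass < max_passes) {
    num_changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) num_changed += st.examine(i) ? 1 : 0;
    } else {
      for (int i = 0; i < n; ++i)
        if (st.alpha[i] > 0 && st.alpha[i] < C)
          num_changed += st.examine(i) ? 1 : 0;
    }
    if (examine_all) examine_all = false;
    else if (num_changed == 0) examine_all = true;
    ++pass;
  }
  return List::create(Named("alpha") = st.alpha, Named("b") = -st.b,
                      Named("passes") = pass);
}

// Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
// [[Rcpp::export]]
arma::mat cpp_sqdist(const arma::mat &A, const arma::mat &B) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * (A * B.t());
  D.each_col() += an;
  D.each_row() += bn.t();
  D.transform([](double v) { return v < 0 ? 0.0 : v; });
  return D;
}
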