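// Compiled kernels for the rotor-period propagator and the exact effective
// Hamiltonian (principal matrix logarithm of a unitary via complex Schur).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Time-ordered propagator over one rotor period tau_r = 1/wr_hz with
// midpoint time slicing. `hn` holds the five Fourier components H^(n),
// n = -2..2, as complex matrices in rad/s.
// [[Rcpp::export]]
arma::cx_mat cpp_propagator(Rcpp::List hn, double wr_hz, int n_slices) {
  std::vector<cx_mat> h(5);
  for (int k = 0; k < 5; ++k) h[k] = Rcpp::as<cx_mat>(hn[k]);
  const uword d = h[0].n_rows;
  const double taur = 1.0 / wr_hz;
  const double dt = taur / n_slices;

  cx_mat U(d, d, fill::eye);
  vec eval(d);
  cx_mat evec(d, d), Hs(d, d);
  const std::complex<double> I(0.0, 1.0);

  for (int j = 0; j < n_slices; ++j) {
    const double t = (j + 0.5) * dt;
    const double ph = 2.0 * M_PI * wr_hz * t;
    Hs = h[2];  // n = 0
    for (int n = -2; n <= 2; ++n) {
      if (n == 0) continue;
      Hs += h[n + 2] * std::exp(I * (double)n * ph);
    }
    Hs = 0.5 * (Hs + Hs.t());  // clear rounding asymmetry before eig_sym
    eig_sym(eval, evec, Hs);
    cx_vec phase = exp(-I * conv_to<cx_vec>::from(eval) * dt);
    U = (evec * diagmat(phase) * evec.t()) * U;
  }
  return U;
}

// Principal-branch effective Hamiltonian from a unitary propagator:
// H = (i / tau_r) ln U, computed from the complex Schur form (diagonal for a
// normal matrix, with an always-unitary similarity), eigenphases folded into
// (-pi, pi] so that eigenvalues in Hz lie in (-wr/2, +wr/2].
// [[Rcpp::export]]
Rcpp::List cpp_unitary_log(const arma::cx_mat& U, double wr_hz) {
  const double taur = 1.0 / wr_hz;
  cx_mat Q, T;
  schur(Q, T, U);
  const uword d = U.n_rows;
  vec E(d);          // rad/s
  double min_gap = datum::inf;
  for (uword j = 0; j < d; ++j) {
    double phi = std::arg(T(j, j));   // in (-pi, pi]
    E(j) = -phi / taur;
    double gap = M_PI - std::fabs(phi);
    if (gap < min_gap) min_gap = gap;
  }
  cx_mat H = Q * diagmat(conv_to<cx_vec>::from(E)) * Q.t();
  H = 0.5 * (H + H.t());  // .t() is conjugate transpose for cx_mat
  bool branch_risk = min_gap < 1e-6 * 2.0 * M_PI;
  return Rcpp::List::create(
    Rcpp::Named("matrix") = H,
    Rcpp::Named("eigen_rad_s") = E,
    Rcpp::Named("branch_risk") = branch_risk);
}

// Eigendecomposition of a complex Hermitian matrix (ascending eigenvalues).
// [[Rcpp::export]]
Rcpp::List cpp_eig_herm(const arma::cx_mat& H) {
  vec eval;
  cx_mat evec;
  eig_sym(eval, evec, H);
  return Rcpp::List::create(
    Rcpp::Named("values") = eval,
    Rcpp::Named("vectors") = evec);
}
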