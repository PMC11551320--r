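// Bloch-McConnell propagation for multi-state chemical exchange.
//
// CEST: the 3N-dimensional magnetization (x, y, z per state) evolves under
// exchange + relaxation + B1 nutation for the saturation period. The
// homogeneous form is used (relaxation toward zero); profiles are normalized
// by the t_relax = 0 reference so the recovery term cancels out of the
// reported quantity.
//
// CPMG: transverse magnetization as a complex N-vector evolves under
// L = i*diag(omega) - diag(R2) + K; an ideal 180 pulse is complex
// conjugation, so one tau-180-2tau-180-tau cycle is
// E(tau) * conj(E(2tau)) * E(tau).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat assemble_cest_generator(const mat& K, const vec& delta_rad,
                                   const vec& r1, const vec& r2, double w1) {
  const uword n = K.n_rows;
  mat A(3 * n, 3 * n, fill::zeros);
  // exchange acts identically on x, y, z of each state
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      for (uword c = 0; c < 3; ++c)
        A(3 * i + c, 3 * j + c) += K(i, j);
  for (uword i = 0; i < n; ++i) {
    const double d = delta_rad(i);
    A(3 * i + 0, 3 * i + 0) += -r2(i);
    A(3 * i + 0, 3 * i + 1) += d;
    A(3 * i + 1, 3 * i + 0) += -d;
    A(3 * i + 1, 3 * i + 1) += -r2(i);
    A(3 * i + 1, 3 * i + 2) += w1;
    A(3 * i + 2, 3 * i + 1) += -w1;
    A(3 * i + 2, 3 * i + 2) += -r1(i);
  }
  return A;
}

// [[Rcpp::export]]
arma::vec bm_cest_cpp(const arma::mat& K, const arma::vec& omega_rad,
                      const arma::vec& r1, const arma::vec& r2,
                      const arma::vec& pops, double w1, double t_relax,
                      const arma::vec& offsets_rad, int obs) {
  const uword n = K.n_rows;
  vec out(offsets_rad.n_elem);
  vec m0(3 * n, fill::zeros);
  for (uword i = 0; i < n; ++i) m0(3 * i + 2) = pops(i);
  const double i0 = pops(obs);
  for (uword k = 0; k < offsets_rad.n_elem; ++k) {
    vec delta = omega_rad - offsets_rad(k);
    mat A = assemble_cest_generator(K, delta, r1, r2, w1);
    try {
      vec mt = expmat(A * t_relax) * m0;
      out(k) = mt(3 * obs + 2) / i0;
    } catch (...) {
      out(k) = datum::nan; // ill-conditioned generator: caller rejects
    }
  }
  return out;
}

// Fixed-step Euler integration of the same ODE; brute-force cross-check for
// the matrix-exponential path.
// [[Rcpp::export]]
arma::vec bm_cest_euler_cpp(const arma::mat& K, const arma::vec& omega_rad,
                            const arma::vec& r1, const arma::vec& r2,
                            const arma::vec& pops, double w1, double t_relax,
                            const arma::vec& offsets_rad, int obs, double dt) {
  const uword n = K.n_rows;
  vec out(offsets_rad.n_elem);
  vec m0(3 * n, fill::zeros);
  for (uword i = 0; i < n; ++i) m0(3 * i + 2) = pops(i);
  const double i0 = pops(obs);
  const int nstep = (int) std::ceil(t_relax / dt);
  const double h = t_relax / nstep;
  for (uword k = 0; k < offsets_rad.n_elem; ++k) {
    vec delta = omega_rad - offsets_rad(k);
    mat A = assemble_cest_generator(K, delta, r1, r2, w1);
    vec m = m0;
    for (int s = 0; s < nstep; ++s) m += h * (A * m);
    out(k) = m(3 * obs + 2) / i0;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec bm_cpmg_cpp(const arma::mat& K, const arma::vec& omega_rad,
                      const arma::vec& r2, const arma::vec& pops,
                      double t_ct, const arma::ivec& ncyc, int obs) {
  const uword n = K.n_rows;
  cx_mat L(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      L(i, j) = cx_double(K(i, j), 0.0);
  for (uword i = 0; i < n; ++i)
    L(i, i) += cx_double(-r2(i), omega_rad(i));
  cx_vec m0(n);
  for (uword i = 0; i < n; ++i) m0(i) = cx_double(pops(i), 0.0);
  const double i0 = pops(obs);

  vec out(ncyc.n_elem);
  for (uword k = 0; k < ncyc.n_elem; ++k) {
    const int nc = ncyc(k);
    if (nc <= 0) { out(k) = 0.0; continue; } // reference plane: no CT period
    const double tau = t_ct / (4.0 * nc);
    try {
      cx_mat e1 = expmat(L * tau);
      cx_mat e2 = conj(expmat(L * (2.0 * tau)));
      cx_mat cycle = e1 * e2 * e1;
      cx_vec m = m0;
      for (int c = 0; c < nc; ++c) m = cycle * m;
      const double inten = std::real(m(obs));
      out(k) = -std::log(inten / i0) / t_ct;
    } catch (...) {
      out(k) = datum::nan;
    }
  }
  return out;
}
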