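// Finite-difference primitives for the reaction-diffusion fields.
// All operators use flux-form differences with zero flux through every
// boundary face (missing neighbours contribute nothing), so row sums of the
// implied linear operator vanish and mass is conserved by diffusion.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// 5-point Laplacian, no-flux boundaries: sum over existing neighbours of
// (u_nb - u_c) / h^2.
static void laplacian_into(const mat& u, double h, mat& out) {
  const uword H = u.n_rows, W = u.n_cols;
  const double ih2 = 1.0 / (h * h);
  for (uword j = 0; j < W; ++j) {
    for (uword i = 0; i < H; ++i) {
      const double c = u(i, j);
      double acc = 0.0;
      if (i > 0)     acc += u(i - 1, j) - c;
      if (i + 1 < H) acc += u(i + 1, j) - c;
      if (j > 0)     acc += u(i, j - 1) - c;
      if (j + 1 < W) acc += u(i, j + 1) - c;
      out(i, j) = acc * ih2;
    }
  }
}

// div(m grad n): face flux (m_i + m_j)/2 * (n_j - n_i)/h, divergence is the
// flux sum over faces divided by h; boundary faces carry zero flux.
static void div_m_grad_n_into(const mat& m, const mat& n, double h, mat& out) {
  const uword H = m.n_rows, W = m.n_cols;
  const double ih2 = 1.0 / (h * h);
  for (uword j = 0; j < W; ++j) {
    for (uword i = 0; i < H; ++i) {
      const double mc = m(i, j), nc = n(i, j);
      double acc = 0.0;
      if (i > 0)     acc += 0.5 * (mc + m(i - 1, j)) * (n(i - 1, j) - nc);
      if (i + 1 < H) acc += 0.5 * (mc + m(i + 1, j)) * (n(i + 1, j) - nc);
      if (j > 0)     acc += 0.5 * (mc + m(i, j - 1)) * (n(i, j - 1) - nc);
      if (j + 1 < W) acc += 0.5 * (mc + m(i, j + 1)) * (n(i, j + 1) - nc);
      out(i, j) = acc * ih2;
    }
  }
}

// [[Rcpp::export(name = ".cpp_laplacian")]]
arma::mat cpp_laplacian(const arma::mat& u, double h) {
  mat out(u.n_rows, u.n_cols);
  laplacian_into(u, h, out);
  return out;
}

// [[Rcpp::export(name = ".cpp_div_m_grad_n")]]
arma::mat cpp_div_m_grad_n(const arma::mat& m, const arma::mat& n, double h) {
  mat out(m.n_rows, m.n_cols);
  div_m_grad_n_into(m, n, h, out);
  return out;
}

// Coupled explicit Euler update of tumour density n and vasculature m over
// `nsub` substeps of size dt.  Drug fields A, d and the grid are frozen for
// the duration (quasi-steady drug transport).  Fields are clipped at zero
// after every substep; returns total clipped mass for diagnostics.
// [[Rcpp::export(name = ".cpp_step_nm")]]
List cpp_step_nm(const arma::mat& n0, const arma::mat& m0,
                 const arma::mat& A, const arma::mat& d,
                 double h, double dt, int nsub,
                 double D_n, double r_n, double n_lim, double alpha_mn,
                 double d_r, double D_m, double alpha, double beta,
                 double gamma, double beta_nm, double alpha_nm, double A_r) {
  mat n = n0, m = m0;
  mat lap_n(n.n_rows, n.n_cols), lap_m(n.n_rows, n.n_cols),
      divterm(n.n_rows, n.n_cols);
  double clipped = 0.0;
  for (int s = 0; s < nsub; ++s) {
    laplacian_into(n, h, lap_n);
    laplacian_into(m, h, lap_m);
    div_m_grad_n_into(m, n, h, divterm);
    const uword N = n.n_elem;
    for (uword k = 0; k < N; ++k) {
      const double nk = n[k], mk = m[k];
      const double logi = 1.0 - nk / n_lim;
      double nn = nk + dt * (D_n * lap_n[k] + r_n * nk * logi +
                             alpha_mn * nk * mk - d_r * nk * d[k]);
      double mm = mk + dt * (D_m * lap_m[k] +
                             mk * (alpha + beta * mk + gamma * mk * mk) +
                             beta_nm * divterm[k] +
                             alpha_nm * nk * logi * mk - A_r * mk * A[k]);
      if (nn < 0.0) { clipped -= nn; nn = 0.0; }
      if (mm < 0.0) { clipped -= mm; mm = 0.0; }
      n[k] = nn; m[k] = mm;
    }
  }
  return List::create(_["n"] = n, _["m"] = m, _["clipped"] = clipped);
}
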