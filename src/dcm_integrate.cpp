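// Fixed-step RK4 integration of the bilinear neuronal state equation
// coupled to the balloon-windkessel hemodynamic cascade.
//
// Neuronal:  dz/dt = J(u) z + C u, with
//   J(u)[r,c] = A[r,c] + sum_j u_j B_j[r,c]          (r != c, Hz)
//   J(u)[r,r] = -0.5 * exp(A[r,r] + sum_j u_j B_j[r,r])
// Hemodynamic (per region, canonical constants, three free log-scalings):
//   ds/dt = z - kappa s - gamma (f - 1)
//   df/dt = s
//   tau dv/dt = f - v^(1/alpha)
//   tau dq/dt = f E(f)/E0 - v^(1/alpha) q / v
//   y = V0 [ k1 (1-q) + k2 (1 - q/v) + k3 (1 - v) ]
// with kappa = 0.64 exp(decay_log), tau = 2 exp(transit_log),
// epsilon = exp(epsilon_log), gamma = 0.32, alpha = 0.32, E0 = 0.4,
// V0 = 4 (% signal), k1 = 4.3 * 40.3 * E0 * TE, k2 = epsilon * 25 * E0 * TE,
// k3 = 1 - epsilon, TE = 0.04 s.
//
// Inputs are piecewise-constant per microtime bin, so the neuronal
// Jacobian and the drive C u are refreshed only when the input row
// changes (boxcar designs have very few distinct input values).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr double kGamma = 0.32;
constexpr double kAlpha = 0.32;
constexpr double kE0    = 0.40;
constexpr double kV0    = 4.0;
constexpr double kTE    = 0.04;
constexpr double kNu0   = 40.3;
constexpr double kR0    = 25.0;

struct State {
  vec z, s, f, v, q;
  explicit State(unsigned n) : z(n, fill::zeros), s(n, fill::zeros),
    f(n, fill::ones), v(n, fill::ones), q(n, fill::ones) {}
  void reset() { z.zeros(); s.zeros(); f.ones(); v.ones(); q.ones(); }
};

struct Deriv {
  vec z, s, f, v, q;
  explicit Deriv(unsigned n) : z(n), s(n), f(n), v(n), q(n) {}
};

inline void derivs(const State& x, const mat& Jn, const vec& Cu,
                   const vec& kappa, const vec& tau, Deriv& d) {
  const double ia = 1.0 / kAlpha;
  d.z = Jn * x.z + Cu;
  d.s = x.z - kappa % x.s - kGamma * (x.f - 1.0);
  d.f = x.s;
  for (uword r = 0; r < x.z.n_elem; ++r) {
    const double fr = x.f[r], vr = x.v[r], qr = x.q[r];
    const double fv = std::pow(vr, ia);            // venous outflow
    const double ef = 1.0 - std::pow(1.0 - kE0, 1.0 / fr);
    d.v[r] = (fr - fv) / tau[r];
    d.q[r] = (fr * ef / kE0 - fv * qr / vr) / tau[r];
  }
}

inline void axpy(State& out, const State& x, double h, const Deriv& d) {
  out.z = x.z + h * d.z; out.s = x.s + h * d.s; out.f = x.f + h * d.f;
  out.v = x.v + h * d.v; out.q = x.q + h * d.q;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".dcm_integrate_cpp")]]
Rcpp::List dcm_integrate_cpp(const arma::mat& A, const arma::cube& B,
                             const arma::mat& C, const arma::mat& hemo,
                             const arma::mat& U, double dt,
                             const arma::uvec& sample_bins,
                             const arma::uvec& run_start_bins,
                             bool return_states = false) {
  const uword n = A.n_rows;
  if (hemo.n_rows != n || hemo.n_cols != 3)
    Rcpp::stop("hemo must be n x 3 (transit_log, decay_log, epsilon_log)");
  if (C.n_rows != n || C.n_cols != U.n_cols)
    Rcpp::stop("C must be n x n_channels");
  if (B.n_slices != (U.n_cols > 0 ? U.n_cols - 1 : 0))
    Rcpp::stop("need one B slice per modulatory channel");
  if (!A.is_finite() || !C.is_finite() || !U.is_finite() || !hemo.is_finite())
    Rcpp::stop("non-finite parameter or input");

  const vec tau   = 2.00 * exp(hemo.col(0));
  const vec kappa = 0.64 * exp(hemo.col(1));
  const vec eps   = exp(hemo.col(2));
  const double k1 = 4.3 * kNu0 * kE0 * kTE;
  const vec k2 = eps * (kR0 * kE0 * kTE);
  const vec k3 = 1.0 - eps;

  const uword n_bins = U.n_rows;
  mat Y(sample_bins.n_elem, n);
  mat Z;
  if (return_states) Z.set_size(n_bins, n);

  State x(n), xt(n);
  Deriv d1(n), d2(n), d3(n), d4(n);
  mat Jn(n, n);
  vec Cu(n);
  rowvec u_cur(U.n_cols);
  bool have_u = false;

  auto record = [&](uword row) {
    for (uword r = 0; r < n; ++r)
      Y(row, r) = kV0 * (k1 * (1.0 - x.q[r]) + k2[r] * (1.0 - x.q[r] / x.v[r]) +
                         k3[r] * (1.0 - x.v[r]));
  };

  uword next_sample = 0, next_run = 0;
  for (uword b = 0; b < n_bins; ++b) {
    if (next_run < run_start_bins.n_elem && run_start_bins[next_run] == b) {
      x.reset();
      ++next_run;
    }
    // record BOLD at the start of bin b (row 1 = scan at t = 0)
    while (next_sample < sample_bins.n_elem && sample_bins[next_sample] == b)
      record(next_sample++);
    if (return_states) Z.row(b) = x.z.t();

    if (!have_u || any(U.row(b) != u_cur)) {
      u_cur = U.row(b);
      have_u = true;
      Jn = A;
      for (uword j = 0; j < B.n_slices; ++j) Jn += u_cur[j + 1] * B.slice(j);
      for (uword r = 0; r < n; ++r) Jn(r, r) = -0.5 * std::exp(Jn(r, r));
      Cu = C * u_cur.t();
    }

    derivs(x, Jn, Cu, kappa, tau, d1);
    axpy(xt, x, dt / 2.0, d1);
    derivs(xt, Jn, Cu, kappa, tau, d2);
    axpy(xt, x, dt / 2.0, d2);
    derivs(xt, Jn, Cu, kappa, tau, d3);
    axpy(xt, x, dt, d3);
    derivs(xt, Jn, Cu, kappa, tau, d4);

    const double h = dt / 6.0;
    x.z += h * (d1.z + 2.0 * d2.z + 2.0 * d3.z + d4.z);
    x.s += h * (d1.s + 2.0 * d2.s + 2.0 * d3.s + d4.s);
    x.f += h * (d1.f + 2.0 * d2.f + 2.0 * d3.f + d4.f);
    x.v += h * (d1.v + 2.0 * d2.v + 2.0 * d3.v + d4.v);
    x.q += h * (d1.q + 2.0 * d2.q + 2.0 * d3.q + d4.q);

    if (x.v.min() <= 0.0)
      Rcpp::stop("hemodynamic integration unstable: blood volume became non-positive (reduce dt)");
    if (x.q.min() <= 0.0)
      Rcpp::stop("hemodynamic integration unstable: deoxyhemoglobin became non-positive (reduce dt)");
    if (!x.z.is_finite())
      Rcpp::stop("neuronal integration diverged (non-finite state)");
  }
  // samples falling exactly at the end of the grid
  while (next_sample < sample_bins.n_elem && sample_bins[next_sample] == n_bins)
    record(next_sample++);
  if (next_sample != sample_bins.n_elem)
    Rcpp::stop("sample bin beyond input grid");

  if (return_states)
    return Rcpp::List::create(Rcpp::Named("bold") = Y, Rcpp::Named("z") = Z);
  return Rcpp::List::create(Rcpp::Named("bold") = Y);
}
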