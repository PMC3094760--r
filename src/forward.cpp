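// Forward (generative) model: linear neuronal network driving a balloon
// hemodynamic model per region, in log-state form.
//
// Neuronal states are propagated exactly over each half-sub-step with a
// matrix exponential (the drive is piecewise constant within an output
// bin); the four hemodynamic log-states are advanced by RK4 with the
// neuronal state evaluated exactly at the sub-step midpoint and end.
// The inner loops are scalar
// (no allocations): the finite-difference Jacobian calls this integrator
// hundreds of times per Gauss-Newton iteration.
//
// State layout per region: x (neuronal), s (vasodilatory signal),
// lf (log flow), lv (log volume), lq (log deoxyhemoglobin).

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// hemodynamic derivatives for one region
// hp: kappa, gamma, tau, alpha, rho, epsilon; H: s, lf, lv, lq
static inline void hderiv(const double* hp, double x, const double* H,
                          double* D) {
  const double s = H[0], lf = H[1], lv = H[2], lq = H[3];
  const double ef = std::exp(lf);
  const double fv = std::exp(lv / hp[3]);
  const double Ef = 1.0 - std::exp(std::log(1.0 - hp[4]) / ef);
  D[0] = hp[5] * x - hp[0] * s - hp[1] * (ef - 1.0);
  D[1] = s * std::exp(-lf);
  D[2] = (ef - fv) * std::exp(-lv) / hp[2];
  D[3] = (ef * Ef / hp[4] - fv * std::exp(lq - lv)) * std::exp(-lq) /
         hp[2];
}

// one-sub-step neuronal propagator for piecewise-constant drive:
// x' = E x + Phi w, E = e^{Ah}, Phi = int_0^h e^{As} ds
static void propagator(const mat& A, double h, mat& E, mat& Phi) {
  const uword n = A.n_rows;
  mat aug(2 * n, 2 * n, fill::zeros);
  aug.submat(0, 0, n - 1, n - 1) = A * h;
  aug.submat(0, n, n - 1, 2 * n - 1) = h * eye(n, n);
  mat E2 = expmat(aug);
  E = E2.submat(0, 0, n - 1, n - 1);
  Phi = E2.submat(0, n, n - 1, 2 * n - 1);
}

// core integrator; drive is T x n (held constant within each output bin);
// hemo_noise is T x 4n (per-bin additive terms on the hemodynamic
// derivatives, region-major: s_1..s_n, lf_1..lf_n, lv, lq) or 0 x 0.
static void forward_core(const mat& Eh, const mat& Phih, const mat& drive,
                         const mat& hemo, const mat& obs, double dt,
                         int nsub, const mat& hemo_noise,
                         bool neuronal_only, bool want_states, mat& signal,
                         mat& states) {
  const uword n = Eh.n_rows, T = drive.n_rows;
  const double h = dt / nsub;
  const bool has_noise = hemo_noise.n_rows == T;

  std::vector<double> hp(6 * n);
  for (uword i = 0; i < n; ++i)
    for (int j = 0; j < 6; ++j) hp[6 * i + j] = hemo(i, j);

  std::vector<double> x(n, 0.0), x1(n), xh(n), H(4 * n, 0.0);
  double k1[4], k2[4], k3[4], k4[4], Htmp[4];

  signal.set_size(T, n);
  if (want_states) states.set_size(T, 5 * n);

  for (uword k = 0; k < T; ++k) {
    for (uword i = 0; i < n; ++i) {
      double yi;
      if (neuronal_only) {
        yi = x[i];
      } else {
        const double lv = H[4 * i + 2], lq = H[4 * i + 3];
        yi = obs(i, 0) * (obs(i, 1) * (1.0 - std::exp(lq)) +
                          obs(i, 2) * (1.0 - std::exp(lq - lv)) +
                          obs(i, 3) * (1.0 - std::exp(lv)));
      }
      signal(k, i) = yi;
      if (want_states) {
        states(k, i) = x[i];
        for (int j = 0; j < 4; ++j)
          states(k, n + j * n + i) = H[4 * i + j];
      }
    }

    for (int sub = 0; sub < nsub; ++sub) {
      // exact neuronal half-steps (dense n x n mat-vec): xh is the exact
      // state at the sub-step midpoint, x1 at its end
      for (uword i = 0; i < n; ++i) {
        double acc = 0.0;
        for (uword j = 0; j < n; ++j)
          acc += Eh(i, j) * x[j] + Phih(i, j) * drive(k, j);
        xh[i] = acc;
      }
      for (uword i = 0; i < n; ++i) {
        double acc = 0.0;
        for (uword j = 0; j < n; ++j)
          acc += Eh(i, j) * xh[j] + Phih(i, j) * drive(k, j);
        x1[i] = acc;
      }
      for (uword i = 0; i < n; ++i) {
        const double* p = &hp[6 * i];
        double* Hi = &H[4 * i];
        const double xm = xh[i];
        hderiv(p, x[i], Hi, k1);
        if (has_noise)
          for (int j = 0; j < 4; ++j) k1[j] += hemo_noise(k, j * n + i);
        for (int j = 0; j < 4; ++j) Htmp[j] = Hi[j] + 0.5 * h * k1[j];
        hderiv(p, xm, Htmp, k2);
        if (has_noise)
          for (int j = 0; j < 4; ++j) k2[j] += hemo_noise(k, j * n + i);
        for (int j = 0; j < 4; ++j) Htmp[j] = Hi[j] + 0.5 * h * k2[j];
        hderiv(p, xm, Htmp, k3);
        if (has_noise)
          for (int j = 0; j < 4; ++j) k3[j] += hemo_noise(k, j * n + i);
        for (int j = 0; j < 4; ++j) Htmp[j] = Hi[j] + h * k3[j];
        hderiv(p, x1[i], Htmp, k4);
        if (has_noise)
          for (int j = 0; j < 4; ++j) k4[j] += hemo_noise(k, j * n + i);
        for (int j = 0; j < 4; ++j)
          Hi[j] += (h / 6.0) * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        x[i] = x1[i];
      }
    }
    for (uword i = 0; i < n; ++i) {
      const double lv = H[4 * i + 2];
      if (!std::isfinite(lv) || !std::isfinite(x[i]) ||
          std::fabs(lv) > 10.0)
        Rcpp::stop("integration diverged at node %d, time %.2f s",
                   (int)i + 1, (k + 1) * dt);
    }
  }
}

// [[Rcpp::export(name = ".dcm_forward_cpp")]]
Rcpp::List dcm_forward_cpp(const arma::mat& A, const arma::mat& drive,
                           const arma::mat& hemo, const arma::mat& obs,
                           double dt, int nsub, const arma::mat& hemo_noise,
                           bool neuronal_only, bool want_states) {
  mat E, Phi, signal, states;
  propagator(A, dt / (2.0 * nsub), E, Phi);
  forward_core(E, Phi, drive, hemo, obs, dt, nsub, hemo_noise,
               neuronal_only, want_states, signal, states);
  if (want_states)
    return Rcpp::List::create(Rcpp::Named("signal") = signal,
                              Rcpp::Named("states") = states);
  return Rcpp::List::create(Rcpp::Named("signal") = signal);
}

// decode the stacked parameter vector
// theta = [vec(A) | vec(C) | log-scalings kappa_1..n | log-scalings tau_1..n]
static void decode_theta(const vec& theta, uword n, uword J,
                         const mat& hemo0, mat& A, mat& C, mat& hemo) {
  uword p = 0;
  A.set_size(n, n);
  for (uword j = 0; j < n; ++j)
    for (uword i = 0; i < n; ++i) A(i, j) = theta(p++);
  C.set_size(n, J);
  for (uword j = 0; j < J; ++j)
    for (uword i = 0; i < n; ++i) C(i, j) = theta(p++);
  hemo = hemo0;
  for (uword i = 0; i < n; ++i) hemo(i, 0) *= std::exp(theta(p + i));
  for (uword i = 0; i < n; ++i) hemo(i, 2) *= std::exp(theta(p + n + i));
}

static mat predict_theta(const vec& theta, uword n, const mat& U,
                         const mat& hemo0, const mat& obs, double dt,
                         int nsub) {
  mat A, C, hemo;
  decode_theta(theta, n, U.n_cols, hemo0, A, C, hemo);
  mat E, Phi;
  propagator(A, dt / (2.0 * nsub), E, Phi);
  mat drive = U * C.t();
  mat signal, states;
  forward_core(E, Phi, drive, hemo, obs, dt, nsub, mat(), false, false,
               signal, states);
  return signal;
}

// [[Rcpp::export(name = ".dcm_predict_cpp")]]
arma::mat dcm_predict_cpp(const arma::vec& theta, int n, const arma::mat& U,
                          const arma::mat& hemo0, const arma::mat& obs,
                          double dt, int nsub) {
  return predict_theta(theta, (uword)n, U, hemo0, obs, dt, nsub);
}

// central finite-difference Jacobian of the stacked prediction
// free_idx: 0-based indices into theta; returns (T n) x length(free_idx).
// The neuronal propagator is rebuilt only for perturbations of the A
// block; input-weight and hemodynamic perturbations reuse the base one.
// [[Rcpp::export(name = ".dcm_jacobian_cpp")]]
arma::mat dcm_jacobian_cpp(const arma::vec& theta, int n_, const arma::mat& U,
                           const arma::mat& hemo0, const arma::mat& obs,
                           double dt, int nsub, const arma::uvec& free_idx,
                           double step) {
  const uword n = (uword)n_, J = U.n_cols, T = U.n_rows;
  mat A0, C0, hemo_base;
  decode_theta(theta, n, J, hemo0, A0, C0, hemo_base);
  mat E0, Phi0;
  propagator(A0, dt / (2.0 * nsub), E0, Phi0);

  mat Jout(T * n, free_idx.n_elem);
  mat sp, sm, states;
  for (uword c = 0; c < free_idx.n_elem; ++c) {
    const uword idx = free_idx(c);
    vec tp = theta, tm = theta;
    tp(idx) += step;
    tm(idx) -= step;
    if (idx < n * n) {
      sp = predict_theta(tp, n, U, hemo0, obs, dt, nsub);
      sm = predict_theta(tm, n, U, hemo0, obs, dt, nsub);
    } else {
      mat Ap, Cp, hp;
      decode_theta(tp, n, J, hemo0, Ap, Cp, hp);
      mat drv = U * Cp.t();
      forward_core(E0, Phi0, drv, hp, obs, dt, nsub, mat(), false, false,
                   sp, states);
      mat Am, Cm, hm;
      decode_theta(tm, n, J, hemo0, Am, Cm, hm);
      drv = U * Cm.t();
      forward_core(E0, Phi0, drv, hm, obs, dt, nsub, mat(), false, false,
                   sm, states);
    }
    Jout.col(c) = vectorise(sp - sm) / (2.0 * step);
  }
  return Jout;
}
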