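#include <Rcpp.h>
using namespace Rcpp;

// EPBD force/energy kernels and the Langevin integrator.
// Units are internal throughout: Angstrom, amu, eV, and the derived time
// unit t0 = A*sqrt(amu/eV); the R wrappers convert fs/ps at the boundary.

static inline void epbd_force(const double* y, int n,
                              const double* D, const double* a,
                              const double* ks, double rho, double beta,
                              double* f) {
  // Morse on-site: V = D (e^{-a y} - 1)^2 ; F = 2 D a e^{-a y} (e^{-a y} - 1)
  for (int i = 0; i < n; ++i) {
    double e = std::exp(-a[i] * y[i]);
    f[i] = 2.0 * D[i] * a[i] * e * (e - 1.0);
  }
  // Stacking: W_j = (k_j/2) (1 + rho e^{-beta (y_j + y_{j-1})}) (y_j - y_{j-1})^2
  for (int j = 1; j < n; ++j) {
    double dy = y[j] - y[j - 1];
    double g  = rho * std::exp(-beta * (y[j] + y[j - 1]));
    // dW/dy through the exponential factor is -(k/2) beta g dy^2 for both
    // sites, so the force contribution is +(k/2) beta g dy^2
    double common = 0.5 * ks[j - 1] * beta * g * dy * dy;
    double harm   = ks[j - 1] * (1.0 + g) * dy;
    f[j]     += -harm + common;
    f[j - 1] +=  harm + common;
  }
}

// [[Rcpp::export]]
NumericVector cpp_total_force(NumericVector y, NumericVector D, NumericVector a,
                              NumericVector ks, double rho, double beta) {
  int n = y.size();
  if (D.size() != n || a.size() != n || ks.size() != n - 1)
    stop("parameter vectors do not match chain length");
  NumericVector f(n);
  epbd_force(REAL(y), n, REAL(D), REAL(a), REAL(ks), rho, beta, REAL(f));
  return f;
}

// [[Rcpp::export]]
double cpp_total_potential(NumericVector y, NumericVector D, NumericVector a,
                           NumericVector ks, double rho, double beta) {
  int n = y.size();
  double v = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = std::exp(-a[i] * y[i]) - 1.0;
    v += D[i] * e * e;
  }
  for (int j = 1; j < n; ++j) {
    double dy = y[j] - y[j - 1];
    v += 0.5 * ks[j - 1] * (1.0 + rho * std::exp(-beta * (y[j] + y[j - 1]))) * dy * dy;
  }
  return v;
}

static inline void reflect(double& y, double& v, double y_floor, double y_wall) {
  // Mirror the position and flip the velocity; loop in case a huge step
  // overshoots both walls (cannot happen at stable dt, but stay safe).
  for (int it = 0; it < 64; ++it) {
    if (y > y_wall)       { y = 2.0 * y_wall  - y; v = -v; }
    else if (y < y_floor) { y = 2.0 * y_floor - y; v = -v; }
    else return;
  }
}

// BAOAB Langevin step sequence. c1 = exp(-gamma dt); the O-substep draws
// one standard normal per site from R's RNG so that set.seed() fully
// determines the trajectory. gamma = 0 gives c1 = 1 and the scheme
// reduces to plain velocity Verlet.
//
// Returns sampled positions (frames x N), optionally velocities, and the
// final state.
// [[Rcpp::export]]
List cpp_simulate(NumericVector y0, NumericVector v0,
                  NumericVector D, NumericVector a, NumericVector ks,
                  double rho, double beta, double mass,
                  double dt, double c1, double kT,
                  int n_equil, int n_prod, int stride,
                  double y_floor, double y_wall, bool store_v) {
  int n = y0.size();
  if (v0.size() != n || D.size() != n || a.size() != n || ks.size() != n - 1)
    stop("state/parameter vectors do not match chain length");
  if (stride < 1 || n_prod < stride) stop("require n_prod >= stride >= 1");

  std::vector<double> y(y0.begin(), y0.end()), v(v0.begin(), v0.end()), f(n);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kT / mass);
  double half_dt = 0.5 * dt, half_dt_m = 0.5 * dt / mass;
  bool stochastic = (c2 > 0.0);

  int n_frames = n_prod / stride;
  NumericMatrix ys(n_frames, n);
  NumericMatrix vs(store_v ? n_frames : 1, store_v ? n : 1);

  RNGScope scope;
  epbd_force(y.data(), n, REAL(D), REAL(a), REAL(ks), rho, beta, f.data());

  int frame = 0;
  long total = (long)n_equil + n_prod;
  for (long step = 0; step < total; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) v[i] += half_dt_m * f[i];
    // A: half drift + walls
    for (int i = 0; i < n; ++i) {
      y[i] += half_dt * v[i];
      reflect(y[i], v[i], y_floor, y_wall);
    }
    // O: Ornstein-Uhlenbeck velocity update (exact)
    if (stochastic) {
      for (int i = 0; i < n; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    } else if (c1 != 1.0) {
      for (int i = 0; i < n; ++i) v[i] *= c1;
    }
    // A: half drift + walls
    for (int i = 0; i < n; ++i) {
      y[i] += half_dt * v[i];
      reflect(y[i], v[i], y_floor, y_wall);
    }
    // B: half kick with fresh force
    epbd_force(y.data(), n, REAL(D), REAL(a), REAL(ks), rho, beta, f.data());
    for (int i = 0; i < n; ++i) v[i] += half_dt_m * f[i];

    long prod_step = step - n_equil + 1;  // 1-based within production
    if (prod_step >= 1 && prod_step % stride == 0) {
      for (int i = 0; i < n; ++i) {
        ys(frame, i) = y[i];
        if (store_v) vs(frame, i) = v[i];
      }
      ++frame;
      if ((frame % 64) == 0) {
        for (int i = 0; i < n; ++i)
          if (!R_finite(y[i]) || !R_finite(v[i]))
            stop("non-finite state at production step %ld: the integration is unstable, reduce dt", prod_step);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i]) || !R_finite(v[i]))
      stop("non-finite final state: the integration is unstable, reduce dt");

  return List::create(_["positions"] = ys,
                      _["velocities"] = store_v ? SEXP(vs) : R_NilValue,
                      _["y_final"] = NumericVector(y.begin(), y.end()),
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}
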