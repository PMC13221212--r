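#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama for the SgLV on the log scale.
//
// d log X_i = (alpha_i + sum_j B_ij X_j - 0.5 * sum_j tau_ij^2) dt
//             + sum_j tau_ij dW_j
//
// The Ito correction makes the noise part exact in distribution; the state is
// exponentiated back, so every step stays strictly positive.  One N-dimensional
// Brownian increment per step is shared across species through tau; increments
// are drawn from R's RNG (norm_rand) so set.seed() gives bitwise-identical
// paths.  Rows are recorded every `thin` steps (step 0 included).
// [[Rcpp::export]]
NumericMatrix sim_glv_em_cpp(NumericVector alpha, NumericMatrix B,
                             NumericMatrix tau, NumericVector x0,
                             double dt, int nsteps, int thin, double cap) {
  const int n = alpha.size();
  const int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, n);
  std::vector<double> x(n), lx(n), halfsig(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = x0[i];
    lx[i] = std::log(x0[i]);
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += tau(i, j) * tau(i, j);
    halfsig[i] = 0.5 * s;
    out(0, i) = x[i];
  }
  const double sqdt = std::sqrt(dt);
  GetRNGstate();
  int rec = 1;
  for (int k = 1; k <= nsteps; ++k) {
    for (int j = 0; j < n; ++j) z[j] = norm_rand() * sqdt;
    for (int i = 0; i < n; ++i) {
      double f = alpha[i];
      for (int j = 0; j < n; ++j) f += B(i, j) * x[j];
      double noise = 0.0;
      for (int j = 0; j < n; ++j) noise += tau(i, j) * z[j];
      lx[i] += (f - halfsig[i]) * dt + noise;
    }
    bool blow = false;
    for (int i = 0; i < n; ++i) {
      x[i] = std::exp(lx[i]);
      if (!std::isfinite(x[i]) || x[i] > cap) blow = true;
    }
    if (blow) {
      PutRNGstate();
      stop("abundance exceeded the blow-up cap at t = %g; "
           "mutualistic (doubly positive) coupling can diverge in finite time",
           k * dt);
    }
    if (k % thin == 0) {
      for (int i = 0; i < n; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  PutRNGstate();
  return out;
}

// Euler-Maruyama for the linearized SDE in the original coordinates:
//   dXt_i = (Theta_i + sum_j A_ij (Xt_j - m_j)) dt + Xt_i sum_j tau_ij dW_j
// RNG consumption matches sim_glv_em_cpp step for step, so the same seed and
// grid couple the two systems through identical Brownian increments.
// [[Rcpp::export]]
NumericMatrix sim_linear_em_cpp(NumericMatrix A, NumericVector Theta,
                                NumericVector m, NumericMatrix tau,
                                NumericVector y0, double dt, int nsteps,
                                int thin) {
  const int n = Theta.size();
  const int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, n);
  std::vector<double> x(n), z(n), xn(n);
  for (int i = 0; i < n; ++i) {
    x[i] = y0[i];
    out(0, i) = x[i];
  }
  const double sqdt = std::sqrt(dt);
  GetRNGstate();
  int rec = 1;
  for (int k = 1; k <= nsteps; ++k) {
    for (int j = 0; j < n; ++j) z[j] = norm_rand() * sqdt;
    for (int i = 0; i < n; ++i) {
      double drift = Theta[i];
      for (int j = 0; j < n; ++j) drift += A(i, j) * (x[j] - m[j]);
      double noise = 0.0;
      for (int j = 0; j < n; ++j) noise += tau(i, j) * z[j];
      xn[i] = x[i] + drift * dt + x[i] * noise;
      if (!std::isfinite(xn[i]))
        stop("linearized path overflowed at t = %g", k * dt);
    }
    x = xn;
    if (k % thin == 0) {
      for (int i = 0; i < n; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  PutRNGstate();
  return out;
}

// Monte-Carlo second moment of the linearized SDE after a pulse: npaths
// independent paths start at m + u, and at every `rec_every`-th step the
// squared distance sum_i (Xt_i - m_i)^2 is accumulated with Welford's
// algorithm.  Returns column 1 = mean of W, column 2 = standard error across
// paths, for times 0, rec_every*dt, 2*rec_every*dt, ...
// [[Rcpp::export]]
NumericMatrix mc_second_moment_cpp(NumericMatrix A, NumericVector Theta,
                                   NumericVector m, NumericMatrix tau,
                                   NumericVector u, double dt, int nsteps,
                                   int npaths, int rec_every) {
  const int n = Theta.size();
  const int nrec = nsteps / rec_every + 1;
  std::vector<double> mean(nrec, 0.0), m2(nrec, 0.0);
  std::vector<double> x(n), z(n), xn(n);
  const double sqdt = std::sqrt(dt);
  GetRNGstate();
  for (int p = 1; p <= npaths; ++p) {
    for (int i = 0; i < n; ++i) x[i] = m[i] + u[i];
    int rec = 0;
    for (int k = 0; k <= nsteps; ++k) {
      if (k % rec_every == 0) {
        double w = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = x[i] - m[i];
          w += d * d;
        }
        double delta = w - mean[rec];
        mean[rec] += delta / p;
        m2[rec] += delta * (w - mean[rec]);
        ++rec;
      }
      if (k == nsteps) break;
      for (int j = 0; j < n; ++j) z[j] = norm_rand() * sqdt;
      for (int i = 0; i < n; ++i) {
        double drift = Theta[i];
        for (int j = 0; j < n; ++j) drift += A(i, j) * (x[j] - m[j]);
        double noise = 0.0;
        for (int j = 0; j < n; ++j) noise += tau(i, j) * z[j];
        xn[i] = x[i] + drift * dt + x[i] * noise;
      }
      x = xn;
    }
  }
  PutRNGstate();
  NumericMatrix out(nrec, 2);
  for (int r = 0; r < nrec; ++r) {
    out(r, 0) = mean[r];
    out(r, 1) = npaths > 1 ? std::sqrt(m2[r] / (npaths - 1) / npaths) : NA_REAL;
  }
  return out;
}
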