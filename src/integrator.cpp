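// Fixed-step RK4 integrator for the spatially uniform corticothalamic-
// basal ganglia delay differential system.
//
// State layout (18 variables):
//   y[0..7]   V_a   soma potentials, population order e r s d1 d2 p1 p2 z (mV)
//   y[8..15]  dV_a/dt
//   y[16]     phi_e cortical axonal field (s^-1)
//   y[17]     dphi_e/dt
//
// Connection rows: target (0..7), source code, delay (units of dt, may be
// fractional, 0 or >= 1), nu (mV s).
// Source codes: 0..7 = Q of that population, 8 = phi_e wave field,
// 9 = external drive phi_n (plus optional white noise), 10 = DBS pulse train.
//
// Delayed quantities are read from per-field ring buffers of end-of-step
// values; RK4 stage times at t + dt/2 and t + dt use linear interpolation
// between buffer samples, whose O(dt^2) error is below the RK4 local error
// for these smooth fields at the default dt = 1e-4 s.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid_rate(double V, double qmax, double theta,
                                  double sigma) {
  return qmax / (1.0 + std::exp(-(V - theta) / sigma));
}

// [[Rcpp::export]]
List ctbg_integrate_core(NumericVector y0, double dt, int nsteps,
                         NumericMatrix conn, NumericVector qmax,
                         NumericVector theta, double sigma, double alpha,
                         double beta, double gamma_e, double phin,
                         double stim_amp, double stim_freq, double stim_width,
                         double stim_onset, NumericVector dV,
                         double noise_sd, int thin) {
  const int NP = 8, NS = 18;
  const int nc = conn.nrow();
  if (y0.size() != NS) stop("state vector must have length 18");
  if (thin < 1) thin = 1;

  double maxd = 0.0;
  for (int c = 0; c < nc; ++c) {
    double d = conn(c, 2);
    if (d < 0) stop("negative delay");
    if (d > 0 && d < 1) stop("delays must be zero or at least one time step");
    int sc = (int)conn(c, 1);
    if (d > 0 && sc > 8) stop("delays are only supported on population sources");
    if (d > maxd) maxd = d;
  }
  const int H = (int)std::ceil(maxd) + 3;  // ring buffer depth

  // history buffers: Q of each population and phi_e, end-of-step values
  std::vector<std::vector<double> > hist(9, std::vector<double>(H));
  double y[NS];
  for (int k = 0; k < NS; ++k) y[k] = y0[k];
  for (int p = 0; p < NP; ++p) {
    double q0 = sigmoid_rate(y[p], qmax[p], theta[p], sigma);
    std::fill(hist[p].begin(), hist[p].end(), q0);
  }
  std::fill(hist[8].begin(), hist[8].end(), y[16]);

  const int nkeep = nsteps / thin + 1;
  NumericMatrix Vout(nkeep, NP);
  NumericVector phie_out(nkeep), phix_out(nkeep);
  for (int p = 0; p < NP; ++p) Vout(0, p) = y[p];
  phie_out[0] = y[16];

  const double ab = alpha * beta, apb = alpha + beta;
  const double g2 = gamma_e * gamma_e;
  const double period = (stim_freq > 0) ? 1.0 / stim_freq : 0.0;
  const bool stim_on = (stim_amp > 0 && stim_freq > 0 && stim_width > 0);

  // top-hat pulse train sampled on the step grid; pulse edges are snapped
  // to sample indices (half-open windows) so that grid-aligned protocols
  // are sample-exact and the series matches the R-side pulse_train()
  auto pulse_at = [&](double t) -> double {
    if (!stim_on) return 0.0;
    double u = t - stim_onset;
    if (u < -dt) return 0.0;
    long i = (long)std::llround(t / dt);
    long j = (long)std::floor(u / period);
    for (long jj = std::max(0L, j - 1); jj <= j + 1; ++jj) {
      double tj = stim_onset + jj * period;
      long ilo = (long)std::ceil(tj / dt - 1e-6);
      long ihi = (long)std::ceil((tj + stim_width) / dt - 1e-6) - 1;
      if (i >= ilo && i <= ihi) return stim_amp;
    }
    return 0.0;
  };

  // value of buffer `b` at continuous index `x` (in steps), x <= current i
  auto hval = [&](int b, double x) -> double {
    long lo = (long)std::floor(x);
    double fr = x - lo;
    long m0 = lo % H; if (m0 < 0) m0 += H;
    long m1 = (lo + 1) % H; if (m1 < 0) m1 += H;
    return (1.0 - fr) * hist[b][m0] + fr * hist[b][m1];
  };

  double k1[NS], k2[NS], k3[NS], k4[NS], yt[NS];
  double Q[NP], drive[NP];

  GetRNGstate();
  int kept = 0;
  for (long i = 0; i < nsteps; ++i) {
    const double t = i * dt;
    const double phin_now =
        (noise_sd > 0) ? phin + noise_sd * norm_rand() : phin;
    // stimulus and noise are sample-and-hold at the step resolution, so the
    // realized drive is exactly the zero-order hold of its grid samples
    const double px_now = pulse_at(t);

    for (int stage = 0; stage < 4; ++stage) {
      const double off = (stage == 0) ? 0.0 : (stage == 3 ? 1.0 : 0.5);
      const double* ys;
      if (stage == 0) {
        ys = y;
      } else {
        const double* kk = (stage == 1) ? k1 : (stage == 2 ? k2 : k3);
        const double h = (stage == 3) ? dt : 0.5 * dt;
        for (int k = 0; k < NS; ++k) yt[k] = y[k] + h * kk[k];
        ys = yt;
      }
      for (int p = 0; p < NP; ++p)
        Q[p] = sigmoid_rate(ys[p], qmax[p], theta[p], sigma);
      for (int p = 0; p < NP; ++p) drive[p] = dV[p];
      for (int c = 0; c < nc; ++c) {
        const int tg = (int)conn(c, 0), sc = (int)conn(c, 1);
        const double d = conn(c, 2), nu = conn(c, 3);
        double val;
        if (d > 0)
          val = hval(sc, (double)i + off - d);
        else if (sc < 8)
          val = Q[sc];
        else if (sc == 8)
          val = ys[16];
        else if (sc == 9)
          val = phin_now;
        else
          val = px_now;
        drive[tg] += nu * val;
      }
      double* kout = (stage == 0) ? k1 : (stage == 1 ? k2 : (stage == 2 ? k3 : k4));
      for (int p = 0; p < NP; ++p) {
        kout[p] = ys[8 + p];
        kout[8 + p] = ab * (drive[p] - ys[p]) - apb * ys[8 + p];
      }
      kout[16] = ys[17];
      kout[17] = g2 * (Q[0] - ys[16]) - 2.0 * gamma_e * ys[17];
    }

    for (int k = 0; k < NS; ++k)
      y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);

    const long j = i + 1;
    const long m = j % H;
    for (int p = 0; p < NP; ++p)
      hist[p][m] = sigmoid_rate(y[p], qmax[p], theta[p], sigma);
    hist[8][m] = y[16];

    for (int k = 0; k < NS; ++k) {
      if (!R_finite(y[k])) {
        PutRNGstate();
        stop("integration diverged (non-finite state) at t = %g s, component %d",
             j * dt, k + 1);
      }
    }
    if (y[16] < -1e-6 * qmax[0] - 1.0 || y[16] > qmax[0] * (1.0 + 1e-6) + 1.0) {
      PutRNGstate();
      stop("cortical field left [0, Q_max] at t = %g s (phi_e = %g)",
           j * dt, y[16]);
    }

    if (j % thin == 0) {
      ++kept;
      for (int p = 0; p < NP; ++p) Vout(kept, p) = y[p];
      phie_out[kept] = y[16];
      phix_out[kept] = pulse_at(j * dt);
    }
  }
  PutRNGstate();

  return List::create(_["V"] = Vout, _["phie"] = phie_out,
                      _["phix"] = phix_out);
}
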