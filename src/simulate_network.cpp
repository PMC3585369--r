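#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step Euler-Maruyama integration of the coupled neural-mass network.
//
// Each population holds three subpopulations (pyramidal P, fast inhibitory
// I, slow inhibitory I') and eight second-order synaptic kernels
//   y'' = (gain * coupling) * x(t) - (w1 + w2) * y' - w1 * w2 * y
// one per pathway (gain, w1, w2 of the source subpopulation's synapse type):
//   0: excitatory onto P   (A, a1, a2)  input C_PP * mP + noise (+ drive/coupling)
//   1: fast inhib onto P   (G, g1, g2)  input C_IP * mI
//   2: slow inhib onto P   (B, b1, b2)  input C_I'P * mI'
//   3: excitatory onto I   (A, a1, a2)  input C_PI * mP
//   4: fast inhib onto I   (G, g1, g2)  input C_II * mI
//   5: slow inhib onto I   (B, b1, b2)  input C_I'I * mI'
//   6: excitatory onto I'  (A, a1, a2)  input C_PI' * mP
//   7: slow inhib onto I'  (B, b1, b2)  input C_I'I' * mI'
// Population n_pop-1 is the subcortical pacemaker: it receives the trapezoid
// drive instead of the stimulus offset, and its pyramidal firing rate enters
// the cortical excitatory kernels with gain `subcortical_gain`.
//
// The stimulus offset (mode 0 none, 1 dc, 2 sinusoid) is added to the
// pyramidal membrane potential before the sigmoid, scaled per subpopulation
// by tcs_gain (defaults 1, 0, 0: interneurons unaffected).

static inline double sigm(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(int n_cortical,
                          NumericVector gains,   // A, B, G
                          NumericVector couplings, // nu_E, nu_B, nu_G
                          NumericVector rates,   // a1,a2,b1,b2,g1,g2
                          NumericVector sig_e0, NumericVector sig_v0,
                          NumericVector sig_r,   // per subpop P, I, I'
                          NumericVector C,       // PP,PI,PI2,IP,II,I2P,I2I,I2I2
                          NumericVector tcs_gain,
                          double subcortical_gain,
                          double drive_period, double drive_ramp_up,
                          double drive_plateau, double drive_ramp_down,
                          double drive_amplitude,
                          double noise_mean, double noise_sd,
                          double dt, double duration, double transient,
                          int stim_mode, double stim_freq,
                          NumericVector offsets) {
  const int n_pop = n_cortical + 1;
  const double A = gains[0] * couplings[0], B = gains[1] * couplings[1],
               G = gains[2] * couplings[2];
  const double a1 = rates[0], a2 = rates[1], b1 = rates[2], b2 = rates[3],
               g1 = rates[4], g2 = rates[5];
  const double C_PP = C[0], C_PI = C[1], C_PI2 = C[2], C_IP = C[3],
               C_II = C[4], C_I2P = C[5], C_I2I = C[6], C_I2I2 = C[7];
  // kernel constants per pathway: gain, w1+w2, w1*w2
  const double kg[8]  = {A, G, B, A, G, B, A, B};
  const double kw1[8] = {a1, g1, b1, a1, g1, b1, a1, b1};
  const double kw2[8] = {a2, g2, b2, a2, g2, b2, a2, b2};
  // kernel input coefficient: (gain * coupling) scales the input rate;
  // second-order section shares w1+w2 and w1*w2
  double ks[8], kp[8], kgain[8];
  for (int k = 0; k < 8; ++k) {
    ks[k] = kw1[k] + kw2[k];
    kp[k] = kw1[k] * kw2[k];
    kgain[k] = kg[k];
  }
  const int n_steps = (int)std::llround(duration / dt);
  const int n_skip = (int)std::llround(transient / dt);
  const int n_keep = n_steps - n_skip;
  if (n_keep <= 0) stop("duration must exceed the transient");

  NumericMatrix y(n_pop, 8), z(n_pop, 8);
  NumericMatrix S(n_cortical, n_keep);
  NumericVector sub_trace(n_keep);
  std::vector<double> mP(n_pop), mI(n_pop), mI2(n_pop);

  const double two_pi = 2.0 * M_PI;
  RNGScope rngscope;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // stimulus offset waveform factor
    double wave = 0.0;
    if (stim_mode == 1) wave = 1.0;
    else if (stim_mode == 2) wave = std::sin(two_pi * stim_freq * t);
    // trapezoid drive for the subcortical population
    double tt = t - drive_period * std::floor(t / drive_period);
    double drive = 0.0;
    if (tt < drive_ramp_up) {
      drive = drive_amplitude * (drive_ramp_up > 0 ? tt / drive_ramp_up : 1.0);
    } else if (tt < drive_ramp_up + drive_plateau) {
      drive = drive_amplitude;
    } else if (tt < drive_ramp_up + drive_plateau + drive_ramp_down) {
      drive = drive_amplitude *
        (1.0 - (tt - drive_ramp_up - drive_plateau) / drive_ramp_down);
    }

    // firing rates from current PSPs
    double mP_sub = 0.0;
    for (int i = 0; i < n_pop; ++i) {
      const double vP = y(i, 0) - y(i, 1) - y(i, 2);
      const double vI = y(i, 3) - y(i, 4) - y(i, 5);
      const double vI2 = y(i, 6) - y(i, 7);
      double dP = 0.0, dI = 0.0, dI2 = 0.0;
      if (i < n_cortical && stim_mode != 0) {
        const double off = offsets[i] * wave;
        dP = tcs_gain[0] * off;
        dI = tcs_gain[1] * off;
        dI2 = tcs_gain[2] * off;
      }
      mP[i] = sigm(vP + dP, sig_e0[0], sig_v0[0], sig_r[0]);
      mI[i] = sigm(vI + dI, sig_e0[1], sig_v0[1], sig_r[1]);
      mI2[i] = sigm(vI2 + dI2, sig_e0[2], sig_v0[2], sig_r[2]);
      if (std::abs(vP) > 1e3 || std::abs(vI) > 1e3 || std::abs(vI2) > 1e3) {
        stop("instability: membrane potential diverged at t = %.3f s "
             "(dt = %g s); reduce dt or the inputs", t, dt);
      }
    }
    mP_sub = mP[n_pop - 1];

    // kernel updates
    for (int i = 0; i < n_pop; ++i) {
      const bool cortical = i < n_cortical;
      const double noise = noise_mean + noise_sd * norm_rand();
      double x0 = C_PP * mP[i] + noise;
      if (cortical) x0 += subcortical_gain * mP_sub;
      else x0 += drive;
      const double x[8] = {
        x0,
        C_IP * mI[i],
        C_I2P * mI2[i],
        C_PI * mP[i],
        C_II * mI[i],
        C_I2I * mI2[i],
        C_PI2 * mP[i],
        C_I2I2 * mI2[i]
      };
      for (int k = 0; k < 8; ++k) {
        const double acc = kgain[k] * x[k] - ks[k] * z(i, k) - kp[k] * y(i, k);
        y(i, k) += dt * z(i, k);
        z(i, k) += dt * acc;
      }
    }

    if (step >= n_skip) {
      const int j = step - n_skip;
      for (int i = 0; i < n_cortical; ++i) {
        S(i, j) = y(i, 0) - y(i, 1) - y(i, 2);
      }
      sub_trace[j] = y(n_pop - 1, 0) - y(n_pop - 1, 1) - y(n_pop - 1, 2);
    }
  }
  return List::create(_["S"] = S, _["subcortical_trace"] = sub_trace);
}
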