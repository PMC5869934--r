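#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the independent-channel stance loop.
//
// States: x0 = theta (body-in-space sway, rad), x1 = dtheta/dt (rad/s),
//         x2 = Tf (low-pass filtered positive force feedback, rad).
// Plant:  J * theta'' = mgh * theta + T_del + d(t)
// Error:  e = W_p * SS - theta + Tf  (earth-fixed surround: visual and
//         vestibular channels both sense -theta, combined weight 1 - W_p)
// PD:     u = K_P * e + K_D * de/dt, applied after a lumped delay of
//         exactly d_samples samples: T_del(t) = u(t - tau_D).
// FF:     tau_F * dTf/dt = K_F * T_del - Tf
//
// The command splits as u(t) = u_s(t) + W_p*(K_P*SS(t) + K_D*SS'(t)).
// The platform feedthrough jumps whenever the ternary velocity switches,
// so it is evaluated exactly at the delayed time (SS is piecewise linear
// with period_samples periodicity); only the smooth remainder u_s is
// buffered at sample instants and linearly interpolated within a step.
//
// Returns theta, the applied (delayed) torque, the commanded torque, and a
// fall index (1-based sample where |theta| first exceeded fall_rad; 0 if
// none).

// [[Rcpp::export]]
List simulate_ic_loop(NumericVector ss_pos, NumericVector ss_vel,
                      NumericVector noise, double fs,
                      double W_p, double K_P, double K_D,
                      double tau_F, double K_F,
                      int d_samples, int period_samples,
                      double J, double mgh,
                      NumericVector init_state,
                      NumericVector init_buffer,
                      double fall_rad) {
  const int n = ss_pos.size();
  const double dt = 1.0 / fs;
  NumericVector theta(n), torque(n), cmd(n);

  // smooth-part command history; index k holds u_s at sample time
  // (k - d_samples)*dt relative to the first output sample, so the first
  // d_samples entries are the pre-trial (steady-state) values supplied by
  // the caller.
  std::vector<double> us(n + d_samples, 0.0);
  for (int k = 0; k < d_samples; ++k) us[k] = init_buffer[k];

  double x0 = init_state[0], x1 = init_state[1], x2 = init_state[2];

  int fall_at = 0;

  // platform feedthrough W_p*(K_P*SS + K_D*SS') at time (i + frac)*dt
  auto feedthrough = [&](int i, double frac) {
    double ss = ss_pos[i] + ss_vel[i] * frac * dt;
    return W_p * (K_P * ss + K_D * ss_vel[i]);
  };
  // same, evaluated d_samples earlier (periodic extension before t = 0)
  auto feedthrough_del = [&](int i, double frac) {
    int idx = i - d_samples;
    if (idx < 0) idx += period_samples;
    double ss = ss_pos[idx] + ss_vel[idx] * frac * dt;
    return W_p * (K_P * ss + K_D * ss_vel[idx]);
  };

  // full commanded torque from the current state at sample i
  auto command = [&](int i, double th, double om, double tf, double tdel) {
    double e  = W_p * ss_pos[i] - th + tf;
    double tfdot = (K_F * tdel - tf) / tau_F;
    double edot = W_p * ss_vel[i] - om + tfdot;
    return K_P * e + K_D * edot;
  };

  // applied (delayed) torque at time (i + frac)*dt, frac in [0, 1]
  auto delayed = [&](int i, double frac) {
    double a = us[i], b = us[i + 1];
    return a + frac * (b - a) + feedthrough_del(i, frac);
  };
  auto disturb = [&](int i, double frac) {
    double a = noise[i];
    double b = (i + 1 < n) ? noise[i + 1] : noise[i];
    return a + frac * (b - a);
  };

  theta[0] = x0;
  double td0 = delayed(0, 0.0);
  torque[0] = td0;
  cmd[0] = command(0, x0, x1, x2, td0);
  us[d_samples] = cmd[0] - feedthrough(0, 0.0);

  for (int i = 0; i < n - 1; ++i) {
    // derivative field at (i + frac)*dt given state (a0, a1, a2)
    auto deriv = [&](double frac, double a0, double a1, double a2,
                     double& d0, double& d1, double& d2) {
      double tdel = delayed(i, frac);
      d0 = a1;
      d1 = (mgh * a0 + tdel + disturb(i, frac)) / J;
      d2 = (K_F * tdel - a2) / tau_F;
    };
    double k10, k11, k12, k20, k21, k22, k30, k31, k32, k40, k41, k42;
    deriv(0.0, x0, x1, x2, k10, k11, k12);
    deriv(0.5, x0 + 0.5 * dt * k10, x1 + 0.5 * dt * k11, x2 + 0.5 * dt * k12,
          k20, k21, k22);
    deriv(0.5, x0 + 0.5 * dt * k20, x1 + 0.5 * dt * k21, x2 + 0.5 * dt * k22,
          k30, k31, k32);
    deriv(1.0, x0 + dt * k30, x1 + dt * k31, x2 + dt * k32, k40, k41, k42);
    x0 += dt / 6.0 * (k10 + 2 * k20 + 2 * k30 + k40);
    x1 += dt / 6.0 * (k11 + 2 * k21 + 2 * k31 + k41);
    x2 += dt / 6.0 * (k12 + 2 * k22 + 2 * k32 + k42);

    theta[i + 1] = x0;
    double tdel = delayed(i + 1, 0.0);
    torque[i + 1] = tdel;
    cmd[i + 1] = command(i + 1, x0, x1, x2, tdel);
    us[i + 1 + d_samples] = cmd[i + 1] - feedthrough(i + 1, 0.0);

    if (fall_at == 0 && std::abs(x0) > fall_rad) {
      fall_at = i + 2;  // 1-based index of the offending sample
      break;
    }
  }

  return List::create(_["theta"] = theta, _["torque"] = torque,
                      _["cmd"] = cmd, _["fall_at"] = fall_at);
}
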