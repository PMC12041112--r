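#include <Rcpp.h>
using namespace Rcpp;

// Per-sample integration of the agent movement policy.
// Uses R's RNG so that set.seed() governs reproducibility.
//
// mode: 0 = drift only, 1 = retreat from the CS until target_dist,
//       2 = approach the CS until approach_stop.
// Positions are horizontal (x, z); head height is constant and appended in R.
// Position noise is Brownian: per-step sd = position_noise_sd * sqrt(dt),
// so the displacement sd over one second is position_noise_sd per axis.
//
// Returns an (n + 1) x 4 matrix of the states at times 0, dt, ..., n * dt:
// time, x, z, yaw (degrees, 0 = +z, increasing toward +x: the left-handed
// y-up heading convention of the logs). Callers sampling a trial of n frames
// use rows 1..n; a single policy step uses the last row.

static const double RAD2DEG = 57.29577951308232;

// [[Rcpp::export]]
NumericMatrix sim_steps_cpp(double x0, double z0, double csx, double csz,
                            int mode, double walk_speed, double target_dist,
                            double approach_stop, double heading_noise_sd,
                            double position_noise_sd, double dt, int n,
                            double xmin, double xmax, double zmin,
                            double zmax) {
  NumericMatrix out(n + 1, 4);
  double x = x0, z = z0;
  double step_sd = position_noise_sd * std::sqrt(dt);
  for (int i = 0; i <= n; ++i) {
    double dxc = csx - x, dzc = csz - z;
    double dist = std::sqrt(dxc * dxc + dzc * dzc);
    // drive velocity (zero when the regulation target is met)
    double vx = 0.0, vz = 0.0;
    if (mode == 1 && dist < target_dist && dist > 1e-12) {
      double gap = target_dist - dist;
      double sp = std::min(walk_speed, gap / dt); // no overshoot
      vx = -dxc / dist * sp;
      vz = -dzc / dist * sp;
    } else if (mode == 2 && dist > approach_stop) {
      double gap = dist - approach_stop;
      double sp = std::min(walk_speed, gap / dt);
      vx = dxc / dist * sp;
      vz = dzc / dist * sp;
    }
    // heading: movement direction while walking, otherwise face the CS
    double yaw;
    double speed = std::sqrt(vx * vx + vz * vz);
    if (speed > 0.05)
      yaw = std::atan2(vx, vz) * RAD2DEG;
    else if (dist > 1e-12)
      yaw = std::atan2(dxc, dzc) * RAD2DEG;
    else
      yaw = 0.0;
    yaw += R::rnorm(0.0, heading_noise_sd);
    yaw -= 360.0 * std::floor(yaw / 360.0); // wrap to [0, 360)

    out(i, 0) = i * dt;
    out(i, 1) = x;
    out(i, 2) = z;
    out(i, 3) = yaw;

    if (i == n) break;
    x += vx * dt + R::rnorm(0.0, step_sd);
    z += vz * dt + R::rnorm(0.0, step_sd);
    if (x < xmin) x = xmin;
    if (x > xmax) x = xmax;
    if (z < zmin) z = zmin;
    if (z > zmax) z = zmax;
  }
  return out;
}
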