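// Overdamped-Langevin metadynamics loop on analytic toy potentials.
// This is the one genuinely loop-bound computation in the package: every
// step needs the gradient of the accumulated bias, an exact sum over all
// deposited hills. Hills farther than 8 sigma contribute < 1e-13 of their
// height and are skipped before the exp() call.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void pot_grad(int pot, const NumericVector& p, const double* x,
                     double* g) {
  switch (pot) {
  case 1: { // double well: V = B ((x/a)^2 - 1)^2
    double B = p[0], a = p[1];
    g[0] = B * 4.0 * x[0] * (x[0] * x[0] / (a * a) - 1.0) / (a * a);
    break;
  }
  case 2: { // harmonic: V = k/2 x^2
    g[0] = p[0] * x[0];
    break;
  }
  case 3: { // triwell (2D): quartic confinement + three Gaussian wells
    double B = p[0], w = p[1];
    double r2 = x[0] * x[0] + x[1] * x[1];
    g[0] = 2.0 * r2 * x[0];
    g[1] = 2.0 * r2 * x[1];
    static const double ang[3] = {M_PI / 2.0, 7.0 * M_PI / 6.0, 11.0 * M_PI / 6.0};
    for (int i = 0; i < 3; ++i) {
      double cx = std::cos(ang[i]), cy = std::sin(ang[i]);
      double dx = x[0] - cx, dy = x[1] - cy;
      double e = std::exp(-(dx * dx + dy * dy) / (2.0 * w * w));
      g[0] += B * e / (w * w) * dx;
      g[1] += B * e / (w * w) * dy;
    }
    break;
  }
  }
}

// [[Rcpp::export]]
List metad_langevin_cpp(int pot, NumericVector pot_params, NumericVector x0,
                        int n_hills, int stride, double dt_ps, double kT,
                        double friction, NumericVector sigma,
                        double h_init, double h_red, int switch_after,
                        int record_every, double bound,
                        int stop_recross, NumericVector basin_r,
                        NumericVector basin_p, int tail_steps,
                        int dwell_steps) {
  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  const double mob = 1.0 / friction;
  const double noise = std::sqrt(2.0 * kT * dt_ps / friction);

  std::vector<double> hc;      // hill centers, d per hill
  std::vector<double> hh;      // heights
  std::vector<double> ht;      // times
  hc.reserve((size_t)n_hills * d);

  std::vector<double> inv2s2(d), cut2(d);
  for (int i = 0; i < d; ++i) {
    inv2s2[i] = 1.0 / (2.0 * sigma[i] * sigma[i]);
    cut2[i] = 64.0 * sigma[i] * sigma[i]; // 8 sigma cutoff, squared
  }

  const long n_steps = (long)n_hills * stride;
  std::vector<double> rec_time, rec_bias;
  std::vector<double> rec_x;
  rec_time.reserve(n_steps / record_every + 2);

  std::vector<double> g(d), gb(d);
  bool diverged = false;
  double diverge_time = 0.0;

  // recrossing bookkeeping on the first CV: phase 0 = not yet in R,
  // 1 = in/after R, 2 = reached P after R; R reached in phase 2 closes
  // one R->P->R cycle. A basin only registers after dwell_steps
  // consecutive in-basin steps, so grazing touches do not count.
  int phase = 0;
  int n_recross = 0;
  int run_r = 0, run_p = 0;

  GetRNGstate();
  long step = 0;
  int deposited = 0;
  double t = 0.0;
  bool stop = false;
  long tail_countdown = -1;  // steps left after the recrossing target is met

  auto bias_grad = [&](const double* xx, double* out) {
    for (int i = 0; i < d; ++i) out[i] = 0.0;
    const size_t nh = hh.size();
    for (size_t h = 0; h < nh; ++h) {
      double expo = 0.0;
      bool far = false;
      for (int i = 0; i < d; ++i) {
        double dd = xx[i] - hc[h * d + i];
        double d2 = dd * dd;
        if (d2 > cut2[i]) { far = true; break; }
        expo += d2 * inv2s2[i];
      }
      if (far) continue;
      double e = hh[h] * std::exp(-expo);
      for (int i = 0; i < d; ++i) {
        double dd = xx[i] - hc[h * d + i];
        out[i] += -e * dd * 2.0 * inv2s2[i]; // d/dx of the Gaussian
      }
    }
  };

  auto bias_value = [&](const double* xx) {
    double v = 0.0;
    const size_t nh = hh.size();
    for (size_t h = 0; h < nh; ++h) {
      double expo = 0.0;
      bool far = false;
      for (int i = 0; i < d; ++i) {
        double dd = xx[i] - hc[h * d + i];
        double d2 = dd * dd;
        if (d2 > cut2[i]) { far = true; break; }
        expo += d2 * inv2s2[i];
      }
      if (!far) v += hh[h] * std::exp(-expo);
    }
    return v;
  };

  while (step < n_steps && !stop) {
    if (tail_countdown == 0) break;
    if (tail_countdown > 0) --tail_countdown;
    // deposit at the start of each stride window after the first
    if (step > 0 && step % stride == 0) {
      ++deposited;
      double h = (deposited <= switch_after) ? h_init : h_red;
      for (int i = 0; i < d; ++i) hc.push_back(x[i]);
      hh.push_back(h);
      ht.push_back(t);
    }

    pot_grad(pot, pot_params, x.data(), g.data());
    bias_grad(x.data(), gb.data());
    for (int i = 0; i < d; ++i) {
      x[i] += -mob * (g[i] + gb[i]) * dt_ps + noise * norm_rand();
    }
    ++step;
    t = step * dt_ps;

    if (std::fabs(x[0]) > bound || (d > 1 && std::fabs(x[1]) > bound)) {
      diverged = true;
      diverge_time = t;
      break;
    }

    if (step % record_every == 0) {
      rec_time.push_back(t);
      for (int i = 0; i < d; ++i) rec_x.push_back(x[i]);
      rec_bias.push_back(bias_value(x.data()));
    }

    if (stop_recross > 0) {
      run_r = (x[0] >= basin_r[0] && x[0] <= basin_r[1]) ? run_r + 1 : 0;
      run_p = (x[0] >= basin_p[0] && x[0] <= basin_p[1]) ? run_p + 1 : 0;
      if (run_r >= dwell_steps) {
        if (phase == 2) {
          ++n_recross;
          if (n_recross >= stop_recross && tail_countdown < 0) {
            tail_countdown = tail_steps;  // settle into the basin before stopping
          }
        }
        phase = 1;
      } else if (run_p >= dwell_steps && phase == 1) {
        phase = 2;
      }
    }
  }
  PutRNGstate();

  const int n_rec = rec_time.size();
  NumericMatrix traj(n_rec, d + 2);
  for (int r = 0; r < n_rec; ++r) {
    traj(r, 0) = rec_time[r];
    for (int i = 0; i < d; ++i) traj(r, 1 + i) = rec_x[(size_t)r * d + i];
    traj(r, d + 1) = rec_bias[r];
  }
  const int nh = hh.size();
  NumericMatrix hills(nh, 2 * d + 2);
  for (int h = 0; h < nh; ++h) {
    hills(h, 0) = ht[h];
    for (int i = 0; i < d; ++i) {
      hills(h, 1 + i) = hc[(size_t)h * d + i];
      hills(h, 1 + d + i) = sigma[i];
    }
    hills(h, 2 * d + 1) = hh[h];
  }
  return List::create(
    _["traj"] = traj, _["hills"] = hills,
    _["diverged"] = diverged, _["diverge_time"] = diverge_time,
    _["n_recross"] = n_recross);
}
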