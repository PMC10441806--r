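#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Monte-Carlo simulation of neurotransmitter diffusion in a 2D synaptic
// cleft with recharging, partially absorbing receptors along the
// postsynaptic density and perfectly absorbing astrocyte walls.
//
// Domain: the cleft [0, c_w] x [0, c_h] with astrocyte walls at
// x = c_w*phi/2 and x = c_w*(1-phi/2). For phi > 0 the walls protrude
// into the cleft. For phi < 0 they sit outside it and the gap between the
// cleft mouth and each wall is an extracellular pocket wrapped by the
// astrocyte flush along the terminal membranes: the pocket keeps the
// cleft's height, its outer wall and its ceiling absorb (astrocyte), its
// floor reflects. This makes the cleft-escape statistics independent of
// the wall distance once the gap exceeds the cleft height, producing the
// strength/width plateau for phi below about -0.2. The cleft's top
// (y = c_h, presynaptic terminal) and bottom (y = 0) reflect, except that
// a particle crossing y = 0 inside a receptor's segment while that
// receptor is in its absorbing state is captured with probability
// k_abs * sqrt(pi * dt / d_coef) (the Robin boundary discretization); the
// receptor then recharges for an exponentially distributed time during
// which its segment reflects.
//
// All particles are released simultaneously at (c_w/2, c_h) and advanced
// jointly (the receptor pool is shared state). The run ends when every
// particle has been absorbed or the time cap is reached.
// [[Rcpp::export]]
List dirt_run_cpp(int n_nt, int n_rec, double tau_r, double k_abs,
                  double d_coef, double c_w, double c_h,
                  double psd1, double psd2, double phi,
                  double dt, double t_cap, int seed) {
  Rng rng(static_cast<std::uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  const double xL = c_w * (phi / 2.0);
  const double xR = c_w * (1.0 - phi / 2.0);
  // the astrocyte wraps flush along the terminal membranes: the pocket
  // ceiling sits at the cleft height and absorbs
  const double h_ex = c_h;
  const double step = std::sqrt(2.0 * d_coef * dt);
  double p_abs = k_abs * std::sqrt(M_PI * dt / d_coef);
  if (p_abs > 1.0) p_abs = 1.0;
  const double rec_w = (n_rec > 0) ? (psd2 - psd1) / n_rec : 0.0;

  std::vector<double> x(n_nt, c_w / 2.0), y(n_nt, c_h);
  // recharge_until[r] <= t means receptor r is in its absorbing state
  std::vector<double> recharge_until(std::max(n_rec, 1), -1.0);

  std::vector<double> rec_times, rec_recover, astro_times;
  rec_times.reserve(n_nt);
  astro_times.reserve(n_nt);

  int alive = n_nt;
  const long n_steps = static_cast<long>(std::ceil(t_cap / dt));
  long s = 0;
  for (; s < n_steps && alive > 0; ++s) {
    const double tnow = (s + 1) * dt;
    for (int i = 0; i < alive; /* increment inside */) {
      double xi = x[i] + step * rng.normal();
      double yi = y[i] + step * rng.normal();

      if (xi <= xL || xi >= xR) {
        // astrocyte wall: perfectly absorbing on first contact
        astro_times.push_back(tnow);
        --alive;
        x[i] = x[alive];
        y[i] = y[alive];
        continue;
      }
      if (yi > h_ex) {
        if (xi > 0.0 && xi < c_w) {
          yi = 2.0 * c_h - yi;  // presynaptic terminal: reflecting top
        } else {
          // pocket ceiling: the astrocyte wrapping along the terminals
          astro_times.push_back(tnow);
          --alive;
          x[i] = x[alive];
          y[i] = y[alive];
          continue;
        }
      }
      if (yi < 0.0) {
        bool captured = false;
        if (n_rec > 0 && xi >= psd1 && xi < psd2) {
          int r = static_cast<int>((xi - psd1) / rec_w);
          if (r >= n_rec) r = n_rec - 1;
          if (recharge_until[r] <= tnow && (p_abs >= 1.0 || rng.unif() < p_abs)) {
            double dur = (tau_r > 0.0) ? rng.expdist(tau_r) : 0.0;
            recharge_until[r] = tnow + dur;
            rec_times.push_back(tnow);
            rec_recover.push_back(tnow + dur);
            captured = true;
          }
        }
        if (captured) {
          --alive;
          x[i] = x[alive];
          y[i] = y[alive];
          continue;
        }
        yi = -yi;  // reflecting bottom (outside PSD or recharging receptor)
      }
      x[i] = xi;
      y[i] = yi;
      ++i;
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["receptor_times"] = rec_times, _["receptor_recover"] = rec_recover,
      _["astro_times"] = astro_times, _["free_at_cap"] = alive,
      _["t_end"] = s * dt);
}

// Splitting-probability helper used by tests: fraction of astrocyte
// absorptions on the left wall, for a 1D-reduction oracle.
// [[Rcpp::export]]
List dirt_exit_sides_cpp(int n_nt, double d_coef, double xL, double xR,
                         double x0, double c_h, double dt, double t_cap,
                         int seed) {
  Rng rng(static_cast<std::uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  const double step = std::sqrt(2.0 * d_coef * dt);
  int left = 0, right = 0;
  const long n_steps = static_cast<long>(std::ceil(t_cap / dt));
  for (int k = 0; k < n_nt; ++k) {
    double x = x0, y = c_h / 2.0;
    for (long s = 0; s < n_steps; ++s) {
      x += step * rng.normal();
      y += step * rng.normal();
      if (x <= xL) { ++left; break; }
      if (x >= xR) { ++right; break; }
      if (y > c_h) y = 2.0 * c_h - y;
      if (y < 0.0) y = -y;
    }
    if ((k & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["left"] = left, _["right"] = right);
}
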