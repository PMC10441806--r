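#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// exp(x) on [-20, 0] by dense lookup + linear interpolation (relative
// error < 4e-6); the spike-generation term is evaluated once per neuron
// per step, so this is the integrator's hottest scalar transcendental.
namespace {
constexpr int EXP_N = 8192;
constexpr double EXP_LO = -20.0;
struct ExpTable {
  double v[EXP_N + 2];
  ExpTable() {
    for (int i = 0; i <= EXP_N + 1; ++i)
      v[i] = std::exp(EXP_LO + (0.0 - EXP_LO) * i / EXP_N);
  }
};
inline double fast_exp_neg(double x) {
  static const ExpTable tab;
  if (x <= EXP_LO) return 0.0;
  if (x >= 0.0) return std::exp(x);  // spike escape: rare, exact
  const double u = (x - EXP_LO) * (EXP_N / (0.0 - EXP_LO));
  const int i = static_cast<int>(u);
  const double f = u - i;
  return tab.v[i] * (1.0 - f) + tab.v[i + 1] * f;
}
}  // namespace

// Forward-Euler integration of a heterogeneous exponential
// integrate-and-fire network.
//
//   dV/dt = -(V - E_L)/tau_m + (Delta_T/tau_m) exp((V - V_T)/Delta_T) + F + R
//
// Spike when V >= V_th at step end: the event is recorded and V is held at
// V_re for the refractory period. Recurrent input is tracked by per-neuron
// per-class exponential filters: each class is a (source population x
// ensheathment state) pair -- plus one class for the feedforward Poisson
// layer -- sharing a synaptic time constant tau_c. A presynaptic spike
// increments the target's class state by j_eff/(tau_c*sqrt(N)) so that one
// spike delivers total integrated input j_eff/sqrt(N) (exactly, under the
// (1 - dt/tau) discrete decay). Spikes take effect on the following step.
//
// edge_ptr holds CSR offsets (0-based) by presynaptic neuron; targets are
// 1-based neuron ids (avoiding an R-side copy for index conversion).
// class_comp maps each filter class to a current component:
// 0 = feedforward, 1 = recurrent E, 2 = recurrent I. Cell parameters and
// the feedforward bias are per-population (E first: neurons 1..n_e), so
// the hot loop runs on population blocks with scalar constants.
// [[Rcpp::export]]
List eif_sim_cpp(IntegerVector edge_ptr, IntegerVector edge_target,
                 IntegerVector edge_class, NumericVector edge_winc,
                 IntegerVector ffwd_ptr, IntegerVector ffwd_target,
                 IntegerVector ffwd_class, NumericVector ffwd_winc,
                 IntegerVector ffwd_spike_step, IntegerVector ffwd_spike_id,
                 NumericVector class_tau, IntegerVector class_comp,
                 NumericMatrix noise, IntegerVector group,
                 NumericVector bias, double sigma_s,
                 int n_e,
                 NumericVector tau_m, NumericVector v_th, NumericVector v_t,
                 NumericVector e_l, NumericVector v_re,
                 NumericVector delta_t, IntegerVector ref_steps,
                 NumericVector v0, double dt, int n_steps,
                 IntegerVector record_ids, int record_stride,
                 bool record_v, double max_spikes,
                 IntegerVector active_classes, NumericMatrix x0) {
  const int N = v0.size();
  const int n_classes = class_tau.size();
  const int n_groups = noise.ncol();
  // classes that can ever receive input; the rest stay identically zero
  std::vector<int> act(active_classes.begin(), active_classes.end());
  const int n_act = static_cast<int>(act.size());

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<int> ref(N, 0);
  // per-neuron initial filter states (rows: class, cols: neuron) -- the
  // stationary mean plus shot-noise jitter, so the run starts inside the
  // fluctuation-driven balanced state rather than below it
  std::vector<std::vector<double>> x(n_classes, std::vector<double>(N, 0.0));
  if (x0.ncol() == N) {
    for (int c = 0; c < n_classes; ++c) {
      for (int j = 0; j < N; ++j) x[c][j] = x0(c, j);
    }
  }
  std::vector<double> decay(n_classes);
  for (int c = 0; c < n_classes; ++c) {
    if (class_tau[c] <= dt)
      stop("synaptic time constant (%.3f ms) must exceed dt", class_tau[c]);
    decay[c] = 1.0 - dt / class_tau[c];
  }

  // recorded-neuron slots
  const int n_rec = record_ids.size();
  std::vector<int> slot(N, -1);
  for (int k = 0; k < n_rec; ++k) slot[record_ids[k]] = k;
  const int n_samples_max =
      (n_rec > 0 && record_stride > 0) ? (n_steps + record_stride - 1) / record_stride : 0;
  NumericMatrix cur_f(n_samples_max, n_rec), cur_e(n_samples_max, n_rec),
      cur_i(n_samples_max, n_rec);
  NumericMatrix volt(record_v ? n_samples_max : 0, record_v ? n_rec : 0);
  std::vector<double> sample_times;
  sample_times.reserve(n_samples_max);

  std::vector<int> spike_id;
  std::vector<double> spike_time;
  std::vector<int> fired;
  fired.reserve(1024);

  const int n_ffwd_spikes = ffwd_spike_step.size();
  int ffwd_cursor = 0;
  bool truncated = false;
  double t_end = n_steps * dt;
  int n_sampled = 0;

  const double* xp[8];
  int comp_of[8];
  for (int a = 0; a < n_act; ++a) {
    xp[a] = x[act[a]].data();
    comp_of[a] = class_comp[act[a]];
  }

  for (int s = 0; s < n_steps; ++s) {
    const double t_next = (s + 1) * dt;
    const bool sampling = (n_rec > 0 && record_stride > 0 && s % record_stride == 0);
    if (sampling) sample_times.push_back(s * dt);
    fired.clear();
    // shared-noise values for this step, hoisted out of the neuron loop
    double g0 = 0.0, g1 = 0.0;
    if (n_groups > 0) g0 = sigma_s * noise(s, 0);
    if (n_groups > 1) g1 = sigma_s * noise(s, 1);

    for (int pop = 0; pop < 2; ++pop) {
      const int j0 = pop == 0 ? 0 : n_e;
      const int j1 = pop == 0 ? n_e : N;
      const double inv_tm = 1.0 / tau_m[pop];
      const double inv_dt_slope = 1.0 / delta_t[pop];
      const double psi_coef = delta_t[pop] / tau_m[pop];
      const double vth = v_th[pop], vt = v_t[pop], el = e_l[pop],
                   vre = v_re[pop], bs = bias[pop];
      const int rs = ref_steps[pop];
      for (int j = j0; j < j1; ++j) {
        double comp_f = 0.0, comp_e = 0.0, comp_i = 0.0;
        for (int a = 0; a < n_act; ++a) {
          const double xv = xp[a][j];
          switch (comp_of[a]) {
            case 0: comp_f += xv; break;
            case 1: comp_e += xv; break;
            default: comp_i += xv; break;
          }
        }
        comp_f += bs + (n_groups > 1 ? (group[j] ? g1 : g0) : g0);

        if (sampling && slot[j] >= 0) {
          cur_f(n_sampled, slot[j]) = comp_f;
          cur_e(n_sampled, slot[j]) = comp_e;
          cur_i(n_sampled, slot[j]) = comp_i;
          if (record_v) volt(n_sampled, slot[j]) = V[j];
        }

        if (ref[j] > 0) {
          --ref[j];
          continue;
        }
        const double vv = V[j];
        const double vexp = vv > vth ? vth : vv;  // clamp inside exp
        const double arg = (vexp - vt) * inv_dt_slope;
        const double psi = psi_coef * fast_exp_neg(arg);
        double vnew =
            vv + dt * (-(vv - el) * inv_tm + psi + comp_f + comp_e + comp_i);
        if (!std::isfinite(vnew))
          stop("membrane potential became non-finite at t = %.2f ms (neuron %d)",
               t_next, j + 1);
        if (vnew >= vth) {
          spike_id.push_back(j + 1);
          spike_time.push_back(t_next);
          fired.push_back(j);
          vnew = vre;
          ref[j] = rs;
        }
        V[j] = vnew;
      }
    }
    if (sampling) ++n_sampled;

    // advance filters, then deliver this step's spikes (effective next step)
    for (int c : act) {
      const double d = decay[c];
      double* xc = x[c].data();
      for (int j = 0; j < N; ++j) xc[j] *= d;
    }
    for (int k : fired) {
      for (int e = edge_ptr[k]; e < edge_ptr[k + 1]; ++e)
        x[edge_class[e]][edge_target[e] - 1] += edge_winc[e];
    }
    while (ffwd_cursor < n_ffwd_spikes && ffwd_spike_step[ffwd_cursor] == s) {
      const int k = ffwd_spike_id[ffwd_cursor];
      for (int e = ffwd_ptr[k]; e < ffwd_ptr[k + 1]; ++e)
        x[ffwd_class[e]][ffwd_target[e] - 1] += ffwd_winc[e];
      ++ffwd_cursor;
    }

    if (static_cast<double>(spike_id.size()) > max_spikes) {
      truncated = true;
      t_end = t_next;
      break;
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  SEXP currents = R_NilValue;
  if (n_rec > 0 && record_stride > 0) {
    currents = List::create(
        _["time"] = NumericVector(sample_times.begin(), sample_times.end()),
        _["ffwd"] = cur_f, _["rec_e"] = cur_e, _["rec_i"] = cur_i,
        _["n_samples"] = n_sampled,
        _["voltage"] = record_v ? (SEXP)volt : R_NilValue);
  }
  return List::create(_["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
                      _["spike_time"] = NumericVector(spike_time.begin(), spike_time.end()),
                      _["truncated"] = truncated, _["t_end"] = t_end,
                      _["currents"] = currents);
}

// SplitMix64-based seed derivation: deterministic, platform-independent
// mapping from an integer vector to a positive 31-bit seed.
// [[Rcpp::export]]
int hash_seed_cpp(IntegerVector keys) {
  std::uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < keys.size(); ++i) {
    h += static_cast<std::uint64_t>(static_cast<std::int64_t>(keys[i])) +
         0x9E3779B97F4A7C15ULL;
    h ^= h >> 30;
    h *= 0xBF58476D1CE4E5B9ULL;
    h ^= h >> 27;
    h *= 0x94D049BB133111EBULL;
    h ^= h >> 31;
  }
  return static_cast<int>(h % 2147483629ULL) + 1;
}
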