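#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Memory-lean per-edge compilation for large networks: class ids (0-based)
// and filter increments j_eff/(tau_class*sqrt(N)) computed in one pass
// without R-level intermediates. Classes: 0 = E unensheathed,
// 1 = E ensheathed, 2 = I unensheathed, 3 = I ensheathed.
// [[Rcpp::export]]
List compile_edges_cpp(IntegerVector pre_ptr, IntegerVector post, int n_e,
                       LogicalVector flags, NumericMatrix j,
                       NumericVector class_tau, double f_j, double sqrt_n) {
  const R_xlen_t n_edges = post.size();
  const int n_neurons = pre_ptr.size() - 1;
  IntegerVector cls(n_edges);
  NumericVector winc(n_edges);
  // winc lookup per (class, post population): 4 classes x 2 target pops
  double table[4][2];
  for (int c = 0; c < 4; ++c) {
    const int src = c / 2;          // 0 = E, 1 = I source
    const bool ens = (c % 2) == 1;
    for (int tgt = 0; tgt < 2; ++tgt) {
      const double j_eff = j(tgt, src) * (ens ? f_j : 1.0);
      table[c][tgt] = j_eff / (class_tau[c] * sqrt_n);
    }
  }
  for (int pre = 0; pre < n_neurons; ++pre) {
    const int base = (pre < n_e) ? 0 : 2;
    for (int e = pre_ptr[pre]; e < pre_ptr[pre + 1]; ++e) {
      const int c = base + (flags[e] ? 1 : 0);
      cls[e] = c;
      winc[e] = table[c][post[e] <= n_e ? 0 : 1];
    }
  }
  return List::create(_["cls"] = cls, _["winc"] = winc);
}
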