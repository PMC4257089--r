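#include <Rcpp.h>
using namespace Rcpp;

// Core stepping loop for a compiled logical network.
//
// Node update semantics per iteration (semi-synchronous):
//   phase 1 (in node order): clamped/forced nodes are skipped; external
//     nodes are resampled ON with probability ext_prob; internal nodes take
//     their rule's truth-table value on the *current* state (synchronous).
//   phase 2 (in node order): clamped nodes -> 0; forced nodes resampled ON
//     with probability forced_prob (overriding any rule).
// With env_fixed = true external nodes hold their initial value instead of
// being resampled.
//
// Uses R's RNG stream, so set.seed() in R fully determines the trajectory.
// Activity is the percentage of ON states over the last `window` of the
// n_iter produced states (the initial state is excluded).

// [[Rcpp::export]]
List simulate_compiled_cpp(List reg_idx, List truth, LogicalVector is_external,
                           NumericVector ext_prob, LogicalVector clamp,
                           LogicalVector forced, NumericVector forced_prob,
                           IntegerVector init_state, int n_iter, int window,
                           bool env_fixed, bool return_trajectory) {
  const int n = init_state.size();
  std::vector<int> state(init_state.begin(), init_state.end());
  std::vector<int> next(n);
  std::vector<double> on_count(n, 0.0);

  // pre-extract regulator indices and truth tables
  std::vector<std::vector<int> > regs(n);
  std::vector<std::vector<int> > tts(n);
  for (int j = 0; j < n; ++j) {
    if (!Rf_isNull(reg_idx[j])) {
      IntegerVector r = reg_idx[j];
      regs[j].assign(r.begin(), r.end());
      IntegerVector t = truth[j];
      tts[j].assign(t.begin(), t.end());
    }
  }

  IntegerMatrix traj;
  if (return_trajectory) {
    traj = IntegerMatrix(n_iter + 1, n);
    for (int j = 0; j < n; ++j) traj(0, j) = state[j];
  }

  RNGScope scope;
  const int window_start = n_iter - window + 1;  // iterations counted from 1

  for (int iter = 1; iter <= n_iter; ++iter) {
    // phase 1
    for (int j = 0; j < n; ++j) {
      if (clamp[j] || forced[j]) { next[j] = state[j]; continue; }
      if (is_external[j]) {
        next[j] = env_fixed ? state[j] : (unif_rand() < ext_prob[j] ? 1 : 0);
      } else {
        int idx = 0;
        const std::vector<int>& r = regs[j];
        for (size_t b = 0; b < r.size(); ++b) idx |= state[r[b]] << b;
        next[j] = tts[j][idx];
      }
    }
    // phase 2: perturbation overrides
    for (int j = 0; j < n; ++j) {
      if (clamp[j]) next[j] = 0;
      else if (forced[j]) next[j] = unif_rand() < forced_prob[j] ? 1 : 0;
    }
    state = next;
    if (return_trajectory) {
      for (int j = 0; j < n; ++j) traj(iter, j) = state[j];
    }
    if (iter >= window_start) {
      for (int j = 0; j < n; ++j) on_count[j] += state[j];
    }
  }

  NumericVector activity(n);
  for (int j = 0; j < n; ++j) activity[j] = 100.0 * on_count[j] / window;

  List out = List::create(_["activity"] = activity);
  if (return_trajectory) out["trajectory"] = traj;
  return out;
}
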