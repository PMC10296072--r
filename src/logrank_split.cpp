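#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Best log-rank split of a survival-tree node on one covariate.
//
// For each candidate threshold c the standardized log-rank statistic
//   L = |sum_i (d_i1 - n_i1 d_i / n_i)| /
//       sqrt(sum_i (n_i1/n_i)(1 - n_i1/n_i)((n_i - d_i)/(n_i - 1)) d_i)
// is accumulated over the node's distinct event times (terms with n_i <= 1
// skipped). A split is valid only if both daughters are non-empty and each
// daughter holds at least min_node_events events. Returns
// (threshold, L, valid) for the best valid candidate.
//
// [[Rcpp::export(name = ".lr_best_split_cpp")]]
NumericVector lr_best_split_cpp(NumericVector time, IntegerVector status,
                                NumericVector x, NumericVector cands,
                                int min_node_events) {
  int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] > time[b]; });

  double best_L = -1.0, best_c = NA_REAL;
  for (int ci = 0; ci < cands.size(); ++ci) {
    double c = cands[ci];
    int nleft = 0, ev_left = 0, ev_right = 0;
    for (int i = 0; i < n; ++i) {
      if (x[i] <= c) {
        ++nleft;
        if (status[i] == 1) ++ev_left;
      } else if (status[i] == 1) ++ev_right;
    }
    if (nleft == 0 || nleft == n) continue;
    if (ev_left < min_node_events || ev_right < min_node_events) continue;

    double num = 0.0, den = 0.0;
    int at_risk = 0, at_risk_left = 0;
    int i = 0;
    while (i < n) {
      double t = time[ord[i]];
      int d = 0, d1 = 0;
      // absorb the whole tie block at time t into the risk set
      while (i < n && time[ord[i]] == t) {
        int j = ord[i];
        ++at_risk;
        if (x[j] <= c) ++at_risk_left;
        if (status[j] == 1) {
          ++d;
          if (x[j] <= c) ++d1;
        }
        ++i;
      }
      if (d > 0 && at_risk > 1) {
        double ni = at_risk, ni1 = at_risk_left, di = d;
        num += d1 - ni1 * di / ni;
        den += (ni1 / ni) * (1.0 - ni1 / ni) * ((ni - di) / (ni - 1.0)) * di;
      }
    }
    if (den <= 0.0) continue;
    double L = std::abs(num) / std::sqrt(den);
    if (L > best_L) {
      best_L = L;
      best_c = c;
    }
  }

  NumericVector out(3);
  out[0] = best_c;
  out[1] = best_L;
  out[2] = best_L >= 0.0 ? 1.0 : 0.0;
  return out;
}
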