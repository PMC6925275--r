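#include <Rcpp.h>
#include <cmath>
#include <climits>
using namespace Rcpp;

// One pass over a single-participant session: softmax choice probability of
// the recorded action under the arbitration model, plus the per-trial
// Pavlovian weight. State (posterior means, counters, log-odds) resets at
// every block boundary. Stimuli are coded 1..4, actions 1 = Go / 0 = No-Go.
// [[Rcpp::export]]
List arb_session_cpp(IntegerVector stim, IntegerVector action,
                     IntegerVector reward, IntegerVector block,
                     double beta, double theta0_u, double eta0_u,
                     double theta0_c, double eta0_c, double L0,
                     bool adaptive, double w_fixed) {
  const int n = stim.size();
  const int S = 4;
  const double eps = 1e-6;
  double th_s[S], eta_s[S], th_go[S], th_ng[S], eta_go[S], eta_ng[S];
  double L = L0;
  int cur_block = INT_MIN;
  double ll = 0.0;
  NumericVector wv(n), pgo(n);

  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {          // new block: fresh stimuli, reset
      cur_block = block[t];
      for (int s = 0; s < S; ++s) {
        th_s[s] = theta0_u; eta_s[s] = eta0_u;
        th_go[s] = theta0_c; th_ng[s] = theta0_c;
        eta_go[s] = eta0_c; eta_ng[s] = eta0_c;
      }
      L = L0;
    }
    const int s = stim[t] - 1;
    const double w = adaptive ? 1.0 / (1.0 + std::exp(-L)) : w_fixed;
    const double vgo = w * th_s[s] + (1.0 - w) * th_go[s];
    const double vng = (1.0 - w) * th_ng[s];
    const double p = 1.0 / (1.0 + std::exp(-beta * (vgo - vng)));
    const int a = action[t];
    const double p_act = (a == 1) ? p : 1.0 - p;
    ll += std::log(std::max(p_act, 1e-300));
    wv[t] = w; pgo[t] = p;

    const int r = reward[t];
    if (adaptive) {                       // prequential: pre-update means
      double ths = std::min(1.0 - eps, std::max(eps, th_s[s]));
      double thsa = (a == 1) ? th_go[s] : th_ng[s];
      thsa = std::min(1.0 - eps, std::max(eps, thsa));
      L += (r == 1) ? std::log(ths / thsa)
                    : std::log((1.0 - ths) / (1.0 - thsa));
    }
    eta_s[s] += 1.0;
    th_s[s] += (r - th_s[s]) / eta_s[s];
    if (a == 1) {
      eta_go[s] += 1.0;
      th_go[s] += (r - th_go[s]) / eta_go[s];
    } else {
      eta_ng[s] += 1.0;
      th_ng[s] += (r - th_ng[s]) / eta_ng[s];
    }
  }
  return List::create(_["loglik"] = ll, _["w"] = wv, _["p_go"] = pgo);
}
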