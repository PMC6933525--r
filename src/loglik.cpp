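#include <Rcpp.h>
using namespace Rcpp;

// Sequential trial-level log-likelihood for one subject's session.
//
// Mirrors the R agent machinery (R/agents.R): model-based values from the
// instructed transition probabilities and a delta-rule reward model, Q-learning
// with an eligibility trace for the single-step model-free values, per-sequence
// model-free caches, and a softmax with stay bonus. The latent sequence/single
// execution of each observed (a1, a2) pair is marginalized:
//   P(a1, a2) = P(sequence a1-a2) + P(single a1) * P(a2 | realized s2).
// Learning updates assume the terminal state reveals the Stage-2 path
// (path-based representation); in the reward-based representation sequence
// reward probabilities are additionally updated from component choices.
//
// a1, a2 in {1, 2}; s2 in {1 = green, 2 = yellow, 3 = red}.

static inline int channel_of(int s2, int a2) {
  return (s2 == 3) ? 4 : (s2 - 1) * 2 + (a2 - 1); // 0-based channel
}

// [[Rcpp::export]]
double loglik_session_cpp(IntegerVector a1, IntegerVector s2, IntegerVector a2,
                          NumericVector reward, NumericVector params,
                          bool uses_seq, bool single_mix, int seq_ctrl,
                          bool expt2, bool reward_based, double common_prob,
                          bool stay_stage2) {
  const int n = a1.size();
  const double alpha = params[0], b1 = params[1], b2 = params[2],
               nu = params[3], omega = params[4], lam = params[5];
  const double cp = common_prob, rp = 1.0 - common_prob;
  const double w_single = single_mix ? omega : 1.0;
  const double w_seq = (seq_ctrl == 2) ? omega : 1.0;

  double qmf1[2] = {0.0, 0.0};
  double qmf2[3][2] = {{0, 0}, {0, 0}, {0, 0}};
  double rprime[5];
  double pseq[4];
  double qmf_seq[4] = {0, 0, 0, 0};
  for (int c = 0; c < 5; ++c) rprime[c] = reward_based ? 0.5 : 0.0;
  for (int k = 0; k < 4; ++k) pseq[k] = 0.5;
  int prev_a1 = 0, prev_a2 = 0; // 0 = none

  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int ia1 = a1[t], is2 = s2[t], ia2 = a2[t];
    if (ia1 < 1 || ia1 > 2 || ia2 < 1 || ia2 > 2 || is2 < 1 || is2 > 3)
      stop("Invalid action/state code at trial %d.", t + 1);

    // model-based stage-2 values
    double q2[3][2];
    for (int s = 0; s < 3; ++s)
      for (int a = 0; a < 2; ++a)
        q2[s][a] = rprime[channel_of(s + 1, a + 1)];
    if (!expt2) { q2[2][0] = 0.0; q2[2][1] = 0.0; }

    // stage-1 option logits: options 0,1 = single L1,R1; 2..5 = sequences
    double logits[6];
    int n_opt = uses_seq ? 6 : 2;
    for (int a = 0; a < 2; ++a) {
      int rs = expt2 ? 2 : 1 - a; // 0-based rare state of action a
      double q1mb = cp * std::max(q2[a][0], q2[a][1]) +
                    rp * std::max(q2[rs][0], q2[rs][1]);
      double q = w_single * q1mb + (1.0 - w_single) * qmf1[a];
      logits[a] = b1 * q + ((prev_a1 == a + 1) ? nu : 0.0);
    }
    if (uses_seq) {
      for (int k = 0; k < 4; ++k) {
        int f = k / 2, sec = k % 2;
        double qmb;
        if (reward_based) {
          qmb = pseq[k];
        } else {
          int rs = expt2 ? 2 : 1 - f;
          qmb = cp * q2[f][sec] + rp * q2[rs][sec];
        }
        double q = w_seq * qmb + (1.0 - w_seq) * qmf_seq[k];
        logits[2 + k] = b1 * q + ((prev_a1 == f + 1) ? nu : 0.0);
      }
    }
    double m = logits[0];
    for (int i = 1; i < n_opt; ++i) m = std::max(m, logits[i]);
    double denom = 0.0;
    for (int i = 0; i < n_opt; ++i) denom += std::exp(logits[i] - m);

    // stage-2 probability of the observed action in the realized state
    double l2[2];
    for (int a = 0; a < 2; ++a) {
      double q = w_single * q2[is2 - 1][a] + (1.0 - w_single) * qmf2[is2 - 1][a];
      l2[a] = b2 * q + ((stay_stage2 && prev_a2 == a + 1) ? nu : 0.0);
    }
    double m2 = std::max(l2[0], l2[1]);
    double p2 = std::exp(l2[ia2 - 1] - m2) /
                (std::exp(l2[0] - m2) + std::exp(l2[1] - m2));

    double p_single = std::exp(logits[ia1 - 1] - m) / denom;
    double p = p_single * p2;
    if (uses_seq) {
      int k = (ia1 - 1) * 2 + (ia2 - 1);
      p += std::exp(logits[2 + k] - m) / denom;
    }
    if (!(p > 0.0) || !R_finite(p))
      stop("Non-finite choice probability at trial %d.", t + 1);
    ll += std::log(p);

    // learning updates (components treated as visible; see docs)
    const double r = reward[t];
    double d1 = std::max(qmf2[is2 - 1][0], qmf2[is2 - 1][1]) - qmf1[ia1 - 1];
    qmf1[ia1 - 1] += alpha * d1;
    double d2 = r - qmf2[is2 - 1][ia2 - 1];
    qmf2[is2 - 1][ia2 - 1] += alpha * d2;
    qmf1[ia1 - 1] += alpha * lam * d2;
    int k = (ia1 - 1) * 2 + (ia2 - 1);
    if (seq_ctrl == 2) qmf_seq[k] += alpha * (r - qmf_seq[k]);
    int ch = channel_of(is2, ia2);
    rprime[ch] += alpha * (r - rprime[ch]);
    if (reward_based && uses_seq) pseq[k] += alpha * (r - pseq[k]);

    prev_a1 = ia1;
    prev_a2 = ia2;
  }
  return ll;
}
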