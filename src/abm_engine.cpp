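// Round engine for the matching-market trust simulation.
//
// One round = matching (unpaired donors pick pooled recipients subject to
// their matching generosity), play (each pair plays the modified trust
// sub-game; unpaired agents collect the isolation payoff), commitment
// (exit-strict donors leave after an observed D, surviving pairs dissolve
// exogenously with probability d).  All randomness goes through R's RNG so
// runs are reproducible with set.seed(); the exported single-step wrappers
// and the generation driver share these internal routines, so composing the
// steps in R consumes the identical draw sequence.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// uniform draw from {0, ..., n-1}
static inline int sample_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? (n - 1) : k;
}

// Fisher-Yates shuffle using R's RNG
static void shuffle_vec(std::vector<int>& v) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = sample_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// partner indices are 1-based; 0 means unpaired. history: 1 = C, 0 = D.
static void match_step(const IntegerVector& match_gen,
                       IntegerVector& d_partner,
                       const IntegerVector& r_history,
                       IntegerVector& r_partner) {
  const int nd = match_gen.size(), nr = r_partner.size();
  std::vector<int> donors;
  donors.reserve(nd);
  for (int i = 0; i < nd; ++i)
    if (d_partner[i] == 0) donors.push_back(i);
  shuffle_vec(donors); // fresh random visiting order every round

  std::vector<int> availC, availD;
  availC.reserve(nr);
  availD.reserve(nr);
  for (int j = 0; j < nr; ++j)
    if (r_partner[j] == 0) (r_history[j] == 1 ? availC : availD).push_back(j);

  for (int di : donors) {
    int pick = -1;
    if (match_gen[di] == 1) { // generous: any pooled recipient
      int total = static_cast<int>(availC.size() + availD.size());
      if (total == 0) continue;
      int k = sample_int(total);
      if (k < static_cast<int>(availC.size())) {
        pick = availC[k];
        availC[k] = availC.back();
        availC.pop_back();
      } else {
        k -= static_cast<int>(availC.size());
        pick = availD[k];
        availD[k] = availD.back();
        availD.pop_back();
      }
    } else { // strict: history C only
      if (availC.empty()) continue;
      int k = sample_int(static_cast<int>(availC.size()));
      pick = availC[k];
      availC[k] = availC.back();
      availC.pop_back();
    }
    d_partner[di] = pick + 1;
    r_partner[pick] = di + 1;
  }
}

static void play_step(const IntegerVector& d_partner,
                      const IntegerVector& r_partner,
                      const NumericVector& r_intent,
                      IntegerVector& r_history,
                      NumericVector& d_payoff, NumericVector& r_payoff,
                      double a, double P, double R, double T) {
  const int nd = d_partner.size(), nr = r_partner.size();
  for (int i = 0; i < nd; ++i) {
    if (d_partner[i] > 0) {
      int j = d_partner[i] - 1;
      bool coop = unif_rand() < r_intent[j];
      bool succ = unif_rand() < a;
      if (succ && coop) {
        d_payoff[i] += R;
        r_payoff[j] += R;
        r_history[j] = 1;
      } else {
        if (succ) r_payoff[j] += T; // successful betrayal
        r_history[j] = 0;           // betrayal and honest failure look alike
      }
    } else {
      d_payoff[i] += P;
    }
  }
  for (int j = 0; j < nr; ++j)
    if (r_partner[j] == 0) r_payoff[j] += P;
}

static void commit_step(const IntegerVector& exit_gen,
                        IntegerVector& d_partner,
                        const IntegerVector& r_history,
                        IntegerVector& r_partner,
                        double d) {
  const int nd = d_partner.size();
  for (int i = 0; i < nd; ++i) {
    if (d_partner[i] == 0) continue;
    int j = d_partner[i] - 1;
    bool dissolve = (r_history[j] == 0 && exit_gen[i] == 0);
    if (!dissolve) dissolve = (unif_rand() < d); // survivors face exogenous risk
    if (dissolve) {
      d_partner[i] = 0;
      r_partner[j] = 0;
    }
  }
}

// [[Rcpp::export]]
List abm_match_cpp(IntegerVector match_gen, IntegerVector d_partner,
                   IntegerVector r_history, IntegerVector r_partner) {
  IntegerVector dp = clone(d_partner), rp = clone(r_partner);
  match_step(match_gen, dp, r_history, rp);
  return List::create(_["d_partner"] = dp, _["r_partner"] = rp);
}

// [[Rcpp::export]]
List abm_play_cpp(IntegerVector d_partner, IntegerVector r_partner,
                  NumericVector r_intent, IntegerVector r_history,
                  NumericVector d_payoff, NumericVector r_payoff,
                  double a, double P, double R, double T) {
  IntegerVector rh = clone(r_history);
  NumericVector dp = clone(d_payoff), rp = clone(r_payoff);
  play_step(d_partner, r_partner, r_intent, rh, dp, rp, a, P, R, T);
  return List::create(_["r_history"] = rh, _["d_payoff"] = dp,
                      _["r_payoff"] = rp);
}

// [[Rcpp::export]]
List abm_commit_cpp(IntegerVector exit_gen, IntegerVector d_partner,
                    IntegerVector r_history, IntegerVector r_partner,
                    double d) {
  IntegerVector dp = clone(d_partner), rp = clone(r_partner);
  commit_step(exit_gen, dp, r_history, rp, d);
  return List::create(_["d_partner"] = dp, _["r_partner"] = rp);
}

// Runs L rounds (match -> play -> commit) and records, right after each
// matching step, the number of pooled recipients and the number of pooled
// recipients with good intent (intent >= good_x_min) but a bad history.
// [[Rcpp::export]]
List abm_generation_cpp(IntegerVector match_gen, IntegerVector exit_gen,
                        IntegerVector d_partner, NumericVector d_payoff,
                        NumericVector r_intent, IntegerVector r_history,
                        IntegerVector r_partner, NumericVector r_payoff,
                        double a, double d, double P, double R, double T,
                        int L, double good_x_min) {
  IntegerVector dpart = clone(d_partner), rhist = clone(r_history),
                rpart = clone(r_partner);
  NumericVector dpay = clone(d_payoff), rpay = clone(r_payoff);
  const int nr = rpart.size();
  IntegerVector iso_recipients(L), iso_good_bad(L);
  for (int t = 0; t < L; ++t) {
    match_step(match_gen, dpart, rhist, rpart);
    int n_iso = 0, n_gb = 0;
    for (int j = 0; j < nr; ++j) {
      if (rpart[j] == 0) {
        ++n_iso;
        if (r_intent[j] >= good_x_min && rhist[j] == 0) ++n_gb;
      }
    }
    iso_recipients[t] = n_iso;
    iso_good_bad[t] = n_gb;
    play_step(dpart, rpart, r_intent, rhist, dpay, rpay, a, P, R, T);
    commit_step(exit_gen, dpart, rhist, rpart, d);
  }
  return List::create(
      _["d_partner"] = dpart, _["d_payoff"] = dpay, _["r_history"] = rhist,
      _["r_partner"] = rpart, _["r_payoff"] = rpay,
      _["iso_recipients"] = iso_recipients, _["iso_good_bad"] = iso_good_bad);
}
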