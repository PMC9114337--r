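// Trial-stepping engine for the hybrid model-free/model-based learner.
// One update routine serves both the generative simulation and the
// likelihood replay, so a replayed session reproduces the simulator's
// internal state sequence exactly.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Agent {
  double q1[2][2];   // Q_MF(first-stage state, action)
  double q2[2];      // Q_MF(planet); 0 = red, 1 = purple
  double tr[2][2];   // P(red | state, action)
  int prev_s1, prev_a, prev_key; // 0 = none

  void init(bool known, const int *map /*planet of action 1 per state*/) {
    for (int s = 0; s < 2; ++s)
      for (int a = 0; a < 2; ++a) {
        q1[s][a] = 4.5;
        tr[s][a] = known ? (((a == 0 ? map[s] : 3 - map[s]) == 1) ? 1.0 : 0.0)
                         : 0.5;
      }
    q2[0] = q2[1] = 4.5;
    prev_s1 = prev_a = prev_key = 0;
  }
};

struct Params {
  double alpha, lam, eta, eta_cf, beta, pi, rho;
  std::vector<double> omega;
};

// Choice probability of action 1 (index 0) in state s1 (0-based), given the
// trial's condition cell (0-based) and side layout (a_left: 0-based action
// shown on the left, pressing key 1).
inline double p_action1(const Agent &ag, const Params &pr, int s1, int cell,
                        int a_left) {
  double v[2];
  for (int a = 0; a < 2; ++a) {
    double qmb = ag.tr[s1][a] * ag.q2[0] + (1.0 - ag.tr[s1][a]) * ag.q2[1];
    double q = (1.0 - pr.omega[cell]) * ag.q1[s1][a] + pr.omega[cell] * qmb;
    double rep = (ag.prev_a == a + 1 && ag.prev_s1 == s1 + 1) ? 1.0 : 0.0;
    int key = (a == a_left) ? 1 : 2;
    double resp = (ag.prev_key == key) ? 1.0 : 0.0;
    v[a] = pr.beta * (q + pr.pi * rep + pr.rho * resp);
  }
  return 1.0 / (1.0 + std::exp(v[1] - v[0]));
}

// Learning updates after a completed first-stage choice.  s2 (0-based
// planet) is always observed once a first-stage choice was made; the reward
// update only happens when the second-stage response was given.
inline void update_after_choice(Agent &ag, const Params &pr, int s1, int a1,
                                int s2, bool stable, bool known, bool miss2,
                                double reward) {
  // stage-1 TD backup at transition time (r = 0, successor = planet value);
  // eligibility traces are reset at trial start, so only (s1, a1) carries
  // credit here, with trace 1
  double delta1 = ag.q2[s2] - ag.q1[s1][a1];
  ag.q1[s1][a1] += pr.alpha * delta1;
  // traces decay by lam: e(s1, a1) = lam, everything else 0

  if (!known) {
    double eta = stable ? 1.0 : pr.eta;
    double eta_cf = stable ? 1.0 : pr.eta_cf;
    // tr stores P(red); move the taken action toward the observed planet
    if (s2 == 0) ag.tr[s1][a1] += eta * (1.0 - ag.tr[s1][a1]);
    else         ag.tr[s1][a1] *= (1.0 - eta);
    int ao = 1 - a1; // other action leads to the other planet
    if (s2 == 0) ag.tr[s1][ao] *= (1.0 - eta_cf);
    else         ag.tr[s1][ao] += eta_cf * (1.0 - ag.tr[s1][ao]);
  }

  if (!miss2) {
    // second-stage reward update; planet states are terminal
    double delta2 = reward - ag.q2[s2];
    ag.q2[s2] += pr.alpha * delta2;
    ag.q1[s1][a1] += pr.alpha * pr.lam * delta2;
  }
}

Params unpack(List par) {
  Params pr;
  pr.alpha = par["alpha"]; pr.lam = par["lam"];
  pr.eta = par["eta"]; pr.eta_cf = par["eta_cf"];
  pr.beta = par["beta"]; pr.pi = par["pi"]; pr.rho = par["rho"];
  pr.omega = as<std::vector<double>>(par["omega"]);
  return pr;
}

} // namespace

// Likelihood replay over a recorded session.  Vectors are per trial; codes:
// s1, a1, key1 in {1, 2} (0 = missing), s2 in {1 = red, 2 = purple, 0},
// reward in 0..9 (-1 = missing), cell 1-based, stable/miss1/miss2 0/1,
// map1/map2 = planet of action 1 in states 1/2 (for known-transition mode).
// [[Rcpp::export]]
List cpp_replay(List par, IntegerVector s1, IntegerVector a1,
                IntegerVector key1, IntegerVector s2, NumericVector reward,
                IntegerVector cell, IntegerVector stable,
                IntegerVector miss1, IntegerVector miss2,
                IntegerVector map1, IntegerVector map2,
                bool known, bool trace) {
  Params pr = unpack(par);
  int n = s1.size();
  Agent ag;
  int map0[2] = {map1.size() ? map1[0] : 1, map2.size() ? map2[0] : 1};
  ag.init(known, map0);

  double ll = 0.0;
  int n_valid = 0;
  NumericVector p_chosen(n, NA_REAL), p_a1(n, NA_REAL);
  NumericMatrix q1_tr, q2_tr, tr_tr;
  if (trace) {
    q1_tr = NumericMatrix(n, 4);
    q2_tr = NumericMatrix(n, 2);
    tr_tr = NumericMatrix(n, 4);
  }

  for (int t = 0; t < n; ++t) {
    if (miss1[t]) {
      ag.prev_s1 = ag.prev_a = ag.prev_key = 0; // indicator reset
    } else {
      int s = s1[t] - 1, a = a1[t] - 1, pl = s2[t] - 1;
      int a_left = (key1[t] == 1) ? a : 1 - a;
      double p1 = p_action1(ag, pr, s, cell[t] - 1, a_left);
      p_a1[t] = p1;
      double pc = (a == 0) ? p1 : 1.0 - p1;
      p_chosen[t] = pc;
      ll += std::log(pc);
      ++n_valid;
      update_after_choice(ag, pr, s, a, pl, stable[t] == 1, known,
                          miss2[t] == 1, reward[t]);
      ag.prev_s1 = s + 1; ag.prev_a = a + 1; ag.prev_key = key1[t];
    }
    if (trace) {
      for (int s = 0; s < 2; ++s)
        for (int aa = 0; aa < 2; ++aa) {
          q1_tr(t, s * 2 + aa) = ag.q1[s][aa];
          tr_tr(t, s * 2 + aa) = ag.tr[s][aa];
        }
      q2_tr(t, 0) = ag.q2[0]; q2_tr(t, 1) = ag.q2[1];
    }
  }

  List out = List::create(_["loglik"] = ll, _["n_valid"] = n_valid,
                          _["p_chosen"] = p_chosen, _["p_action1"] = p_a1);
  if (trace) {
    out["q1"] = q1_tr; out["q2"] = q2_tr; out["trans"] = tr_tr;
  }
  return out;
}

// Generative simulation over a trial plan.  u_choice/u_miss1/u_miss2 are
// uniform(0,1) draws supplied by the caller (R-side RNG); a_left gives the
// side layout (which action is displayed left, 1-based).
// [[Rcpp::export]]
List cpp_simulate(List par, IntegerVector s1, IntegerVector cell,
                  IntegerVector stable, IntegerVector map1,
                  IntegerVector map2, IntegerVector rew_red,
                  IntegerVector rew_purple, NumericVector u_choice,
                  NumericVector u_miss1, NumericVector u_miss2,
                  IntegerVector a_left, double missing_rate, bool known) {
  Params pr = unpack(par);
  int n = s1.size();
  Agent ag;
  int map0[2] = {map1[0], map2[0]};
  ag.init(known, map0);

  IntegerVector a1(n), key1(n), s2(n), miss1(n), miss2(n);
  NumericVector reward(n), p_a1(n);

  for (int t = 0; t < n; ++t) {
    if (missing_rate > 0 && u_miss1[t] < missing_rate) {
      miss1[t] = 1; a1[t] = NA_INTEGER; key1[t] = NA_INTEGER;
      s2[t] = NA_INTEGER; reward[t] = NA_REAL; p_a1[t] = NA_REAL;
      ag.prev_s1 = ag.prev_a = ag.prev_key = 0;
      continue;
    }
    int s = s1[t] - 1, al = a_left[t] - 1;
    double p1 = p_action1(ag, pr, s, cell[t] - 1, al);
    p_a1[t] = p1;
    int a = (u_choice[t] < p1) ? 0 : 1;
    a1[t] = a + 1;
    key1[t] = (a == al) ? 1 : 2;
    int dest1 = (s == 0) ? map1[t] : map2[t]; // planet of action 1
    int pl = (a == 0) ? dest1 : 3 - dest1;    // 1-based planet reached
    s2[t] = pl;
    bool m2 = missing_rate > 0 && u_miss2[t] < missing_rate;
    miss2[t] = m2 ? 1 : 0;
    double r = (pl == 1) ? rew_red[t] : rew_purple[t];
    reward[t] = m2 ? NA_REAL : r;
    update_after_choice(ag, pr, s, a, pl - 1, stable[t] == 1, known, m2, r);
    ag.prev_s1 = s + 1; ag.prev_a = a + 1; ag.prev_key = key1[t];
  }

  return List::create(_["a1"] = a1, _["key1"] = key1, _["s2"] = s2,
                      _["reward"] = reward, _["missing_stage1"] = miss1,
                      _["missing_stage2"] = miss2, _["p_action1"] = p_a1);
}
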