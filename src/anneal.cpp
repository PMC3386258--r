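#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Raw draws from mt19937 so results do not depend on the standard library's
// distribution implementations.
static inline double unif01(std::mt19937 &rng) {
  return (rng() + 0.5) * (1.0 / 4294967296.0);
}
static inline int unif_int(std::mt19937 &rng, int n) {
  // n is small here; modulo bias is negligible and deterministic
  return static_cast<int>(rng() % static_cast<unsigned>(n));
}

// One annealing chain over the Potts assignment state.
//
// Maximizes E(sigma) = sum_{uu edges} w_ij * delta(sigma_i, sigma_j)
//                    + sum_i h(i, sigma_i).
//
// schedule = "gsa": Tsallis-Stariolo visiting temperature
//   T_qv(s) = t0 * (2^(qv-1) - 1) / ((1+s)^(qv-1) - 1), acceptance
//   temperature T_a = T_qv / s, generalized acceptance
//   p = [1 + (qa-1) dC / T_a]^(1/(1-qa)) for dC > 0 (0 when the base is
//   non-positive), with the qa -> 1 limit exp(-dC/T_a).
//   Schedule time s advances once per sweep (n proposals) and wraps every
//   cycle_sweeps sweeps (reannealing), so a long chain is a sequence of
//   hot-to-cold anneal cycles continuing from the current state.
// schedule = "metropolis": geometric cooling per sweep,
//   T = t0 * cool^floor(t/n), classical exp(-dC/T) acceptance, no cycles.
//
// Proposal: pick an uncharacterized node uniformly. In the GSA schedule the
// hot phase acts like the heavy-tailed visiting distribution: with
// probability T_qv(s)/t0 the new label is uniform over the full alphabet;
// otherwise (and always under "metropolis") it is uniform over the node's
// candidate set = {terms with positive field} union {current labels of
// uncharacterized neighbors}, falling back to the full alphabet when that
// set is empty.
// [[Rcpp::export]]
List anneal_chain(NumericMatrix h,
                  IntegerVector uu_i, IntegerVector uu_j, NumericVector uu_w,
                  IntegerVector init, List cand_static,
                  int n_steps, double t0, double qv, double qa,
                  std::string schedule, double cool, int seed,
                  int traj_every, int cycle_sweeps) {
  const int n = h.nrow();
  const int K = h.ncol();
  List out;
  if (n == 0 || K == 0) {
    out["best_labels"] = IntegerVector(0);
    out["best_score"] = 0.0;
    out["final_labels"] = IntegerVector(0);
    out["traj_step"] = IntegerVector::create(0);
    out["traj_best"] = NumericVector::create(0.0);
    return out;
  }

  // CSR adjacency over uncharacterized nodes
  const int m = uu_i.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { ++deg[uu_i[e] - 1]; ++deg[uu_j[e] - 1]; }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> nbr(start[n]);
  std::vector<double> nw(start[n]);
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int e = 0; e < m; ++e) {
      int a = uu_i[e] - 1, b = uu_j[e] - 1;
      double w = uu_w[e];
      nbr[fill[a]] = b; nw[fill[a]] = w; ++fill[a];
      nbr[fill[b]] = a; nw[fill[b]] = w; ++fill[b];
    }
  }

  // static candidate lists (0-based)
  std::vector<std::vector<int>> cstat(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ci = cand_static[i];
    cstat[i].assign(ci.begin(), ci.end());
    for (size_t k = 0; k < cstat[i].size(); ++k) cstat[i][k] -= 1;
  }

  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = init[i] - 1;

  // initial energy
  double E = 0.0;
  for (int e = 0; e < m; ++e)
    if (lab[uu_i[e] - 1] == lab[uu_j[e] - 1]) E += uu_w[e];
  for (int i = 0; i < n; ++i) E += h(i, lab[i]);

  std::vector<int> best_lab(lab);
  double bestE = E;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> stamp(K, -1);
  std::vector<int> cand;
  cand.reserve(K);

  const double qv1 = qv - 1.0;
  const double gsa_num = t0 * (std::pow(2.0, qv1) - 1.0);

  std::vector<int> traj_step;
  std::vector<double> traj_best;
  if (traj_every < 1) traj_every = 1;
  if (cycle_sweeps < 1) cycle_sweeps = 1;
  const bool is_gsa = (schedule == "gsa");

  for (int t = 1; t <= n_steps; ++t) {
    // schedule time: sweep counter, wrapped into reannealing cycles (GSA)
    int sweep = (t - 1) / n;
    double s = is_gsa ? (double)(sweep % cycle_sweeps) + 1.0 : 0.0;
    double Tqv = 0.0, Ta = 0.0;
    if (is_gsa) {
      Tqv = gsa_num / (std::pow(1.0 + s, qv1) - 1.0);
      Ta = Tqv / s;
    } else {
      Ta = t0 * std::pow(cool, (double)sweep);
    }

    int i = unif_int(rng, n);
    int cur = lab[i];

    int prop;
    bool global_move = is_gsa && unif01(rng) < (Tqv / t0);
    if (global_move) {
      prop = unif_int(rng, K);
    } else {
      // candidate labels: positive-field terms + labels of unchar neighbors
      cand.clear();
      for (size_t k = 0; k < cstat[i].size(); ++k) {
        int f = cstat[i][k];
        if (stamp[f] != t) { stamp[f] = t; cand.push_back(f); }
      }
      for (int p = start[i]; p < start[i + 1]; ++p) {
        int f = lab[nbr[p]];
        if (stamp[f] != t) { stamp[f] = t; cand.push_back(f); }
      }
      if (cand.empty()) prop = unif_int(rng, K);
      else prop = cand[unif_int(rng, (int)cand.size())];
    }

    if (prop != cur) {
      double dE = h(i, prop) - h(i, cur);
      for (int p = start[i]; p < start[i + 1]; ++p) {
        int lj = lab[nbr[p]];
        if (lj == prop) dE += nw[p];
        else if (lj == cur) dE -= nw[p];
      }

      bool accept;
      if (dE >= 0.0) {
        accept = true;
      } else {
        double dC = -dE;
        double p_acc;
        if (is_gsa && qa != 1.0) {
          double base = 1.0 + (qa - 1.0) * dC / Ta;
          p_acc = (base <= 0.0) ? 0.0 : std::pow(base, 1.0 / (1.0 - qa));
        } else {
          p_acc = std::exp(-dC / Ta);
        }
        accept = unif01(rng) < p_acc;
      }

      if (accept) {
        lab[i] = prop;
        E += dE;
        if (E > bestE) { bestE = E; best_lab = lab; }
      }
    }

    if (t % traj_every == 0 || t == n_steps) {
      traj_step.push_back(t);
      traj_best.push_back(bestE);
    }
  }

  // recompute the best score from the best labels (guards drift of the
  // incremental accumulator)
  double bestE_exact = 0.0;
  for (int e = 0; e < m; ++e)
    if (best_lab[uu_i[e] - 1] == best_lab[uu_j[e] - 1]) bestE_exact += uu_w[e];
  for (int i = 0; i < n; ++i) bestE_exact += h(i, best_lab[i]);

  IntegerVector best_out(n), final_out(n);
  for (int i = 0; i < n; ++i) { best_out[i] = best_lab[i] + 1; final_out[i] = lab[i] + 1; }

  out["best_labels"] = best_out;
  out["best_score"] = bestE_exact;
  out["final_labels"] = final_out;
  out["traj_step"] = IntegerVector(traj_step.begin(), traj_step.end());
  out["traj_best"] = NumericVector(traj_best.begin(), traj_best.end());
  return out;
}
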