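// Round engine: activity sampling, neighbour matching, CPD interactions,
// emotion/mood updates, trace encoding with exponential forgetting,
// mood-congruent retrieval with refresh, and gist broadcast.
//
// Memory is a bucket store keyed by (owner, counterpart); each bucket holds
// parallel arrays of trace fields. Purging runs lazily on queried buckets
// (deletion depends only on elapsed time, so lazy and eager purging agree)
// plus a periodic global sweep to bound the footprint.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Bucket {
  std::vector<float> coop, emo, phi0;
  std::vector<int> enc;
  std::vector<char> firsthand;
  size_t size() const { return coop.size(); }
  void push(double c, double e, double p, int t, bool fh) {
    coop.push_back((float)c);
    emo.push_back((float)e);
    phi0.push_back((float)p);
    enc.push_back(t);
    firsthand.push_back(fh ? 1 : 0);
  }
  void erase_dead(const std::vector<char>& dead) {
    size_t k = 0;
    for (size_t i = 0; i < size(); ++i) {
      if (!dead[i]) {
        coop[k] = coop[i]; emo[k] = emo[i]; phi0[k] = phi0[i];
        enc[k] = enc[i]; firsthand[k] = firsthand[i];
        ++k;
      }
    }
    coop.resize(k); emo.resize(k); phi0.resize(k);
    enc.resize(k); firsthand.resize(k);
  }
};

double strength(const Bucket& b, size_t i, int t, double theta) {
  return (double)b.phi0[i] * std::exp(-theta * (double)(t - b.enc[i]));
}

void purge_bucket(Bucket& b, int t, double theta, double phi_min) {
  if (b.size() == 0) return;
  std::vector<char> dead(b.size(), 0);
  bool any = false;
  for (size_t i = 0; i < b.size(); ++i) {
    if (strength(b, i, t, theta) < phi_min) { dead[i] = 1; any = true; }
  }
  if (any) b.erase_dead(dead);
}

double encode_phi0(double emotion, double kN, double kP, double c0) {
  return emotion <= 0 ? (-kN * emotion + c0) : (kP * emotion + c0);
}

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(int n, IntegerVector type_int, NumericVector beta0,
                 NumericVector kappa, NumericVector mood0,
                 NumericVector lambda, NumericVector omega_mean,
                 NumericVector drive, List adjacency,
                 NumericVector forget_rate, NumericVector min_strength,
                 NumericVector grad_neg, NumericVector grad_pos,
                 NumericVector intercept, NumericVector gamma,
                 int n_rounds, int omega_resample_every,
                 double C, double T, double D, double S, double beta_max,
                 bool cold_uniform, double cold_value, bool do_broadcast,
                 IntegerVector stream_seeds) {
  // adjacency to 0-based
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adjacency[i];
    nbr[i].reserve(v.size());
    for (int j = 0; j < v.size(); ++j) nbr[i].push_back(v[j] - 1);
  }

  std::vector<Bucket> mem((size_t)n * n);
  auto bucket = [&](int owner, int cp) -> Bucket& {
    return mem[(size_t)owner * n + cp];
  };

  std::mt19937_64 rng_act(stream_seeds[0]);
  std::mt19937_64 rng_pair(stream_seeds[1]);
  std::mt19937_64 rng_ret(stream_seeds[2]);
  std::mt19937_64 rng_rhythm(stream_seeds[3]);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> mood(mood0.begin(), mood0.end());
  std::vector<double> beta_t(beta0.begin(), beta0.end());
  std::vector<double> omega(n, 0.0);
  std::vector<double> payoff_cum(n, 0.0);
  std::vector<int> n_inter(n, 0), n_active_rounds(n, 0);

  // event log
  std::vector<int> ev_round, ev_a, ev_b;
  std::vector<double> ev_ca, ev_cb, ev_pa, ev_pb, ev_ea, ev_eb;
  long long total_gists = 0;

  std::vector<char> active(n), matched(n);
  std::vector<int> active_ids; active_ids.reserve(n);
  std::vector<int> cands; cands.reserve(n);

  // retrieval: returns mean cooperation of retrieved traces via ok/sum,
  // refreshing the retrieved traces in place
  auto retrieve = [&](int owner, int cp, int t, double& mean_c, bool& any) {
    Bucket& b = bucket(owner, cp);
    purge_bucket(b, t, forget_rate[owner], min_strength[owner]);
    double g = gamma[owner], m = mood[owner];
    double sum = 0.0; int cnt = 0;
    for (size_t i = 0; i < b.size(); ++i) {
      double p = 1.0 - g * std::fabs((double)b.emo[i] - m);
      if (p < 0.0) p = 0.0;
      bool hit = p >= 1.0 ? true : (p > 0.0 && unif(rng_ret) < p);
      if (hit) {
        sum += (double)b.coop[i];
        ++cnt;
        b.enc[i] = t; // refresh: strength back to phi0
      }
    }
    any = cnt > 0;
    mean_c = any ? sum / cnt : 0.0;
  };

  auto cold = [&]() {
    return cold_uniform ? unif(rng_ret) : cold_value;
  };

  for (int t = 1; t <= n_rounds; ++t) {
    // bipolar rhythm: resample omega periodically, recompute mood and beta
    for (int i = 0; i < n; ++i) {
      if (type_int[i] == 4) {
        if ((t - 1) % omega_resample_every == 0) {
          std::exponential_distribution<double> ed(1.0 / omega_mean[i]);
          omega[i] = ed(rng_rhythm);
        }
        double m = std::sin(omega[i] * (double)t) + lambda[i];
        if (m > 1.0) m = 1.0;
        if (m < -1.0) m = -1.0;
        mood[i] = m;
        beta_t[i] = (m == 0.0) ? 1.0 : (m < 0.0 ? m + 1.0 : 1.0 + m * (beta_max - 1.0));
      }
    }

    // activity
    active_ids.clear();
    for (int i = 0; i < n; ++i) {
      active[i] = unif(rng_act) < drive[i] ? 1 : 0;
      matched[i] = 0;
      if (active[i]) { active_ids.push_back(i); ++n_active_rounds[i]; }
    }

    // pairing: random order, each unmatched agent grabs a random
    // unmatched active neighbour
    for (size_t i = active_ids.size(); i > 1; --i) {
      std::uniform_int_distribution<size_t> d(0, i - 1);
      std::swap(active_ids[i - 1], active_ids[d(rng_pair)]);
    }
    std::vector<std::pair<int,int>> pairs;
    for (int a : active_ids) {
      if (matched[a]) continue;
      cands.clear();
      for (int x : nbr[a]) {
        if (active[x] && !matched[x]) cands.push_back(x);
      }
      if (cands.empty()) continue;
      int b;
      if (cands.size() == 1) {
        b = cands[0];
      } else {
        std::uniform_int_distribution<size_t> d(0, cands.size() - 1);
        b = cands[d(rng_pair)];
      }
      matched[a] = matched[b] = 1;
      pairs.emplace_back(a, b);
    }

    // interactions
    for (auto& pr : pairs) {
      int a = pr.first, b = pr.second;
      double ea_c, eb_c; bool any_a, any_b;
      retrieve(a, b, t, ea_c, any_a);
      retrieve(b, a, t, eb_c, any_b);
      double c_a = any_a ? ea_c : cold();
      double c_b = any_b ? eb_c : cold();

      double p_a = c_a * c_b * C + c_a * (1 - c_b) * S +
                   (1 - c_a) * c_b * T + (1 - c_a) * (1 - c_b) * D;
      double p_b = c_b * c_a * C + c_b * (1 - c_a) * S +
                   (1 - c_b) * c_a * T + (1 - c_b) * (1 - c_a) * D;
      payoff_cum[a] += p_a; payoff_cum[b] += p_b;
      ++n_inter[a]; ++n_inter[b];

      double d_a = std::tanh(beta_t[a] * c_b - c_a);
      double d_b = std::tanh(beta_t[b] * c_a - c_b);

      bucket(a, b).push(c_b, d_a, encode_phi0(d_a, grad_neg[a], grad_pos[a], intercept[a]), t, true);
      bucket(b, a).push(c_a, d_b, encode_phi0(d_b, grad_neg[b], grad_pos[b], intercept[b]), t, true);

      // mood update (bipolar mood is rhythm-driven instead)
      if (type_int[a] != 4) mood[a] = std::tanh(mood[a] + kappa[a] * (d_a - mood[a]));
      if (type_int[b] != 4) mood[b] = std::tanh(mood[b] + kappa[b] * (d_b - mood[b]));

      ev_round.push_back(t); ev_a.push_back(a + 1); ev_b.push_back(b + 1);
      ev_ca.push_back(c_a); ev_cb.push_back(c_b);
      ev_pa.push_back(p_a); ev_pb.push_back(p_b);
      ev_ea.push_back(d_a); ev_eb.push_back(d_b);

      if (do_broadcast) {
        // neighbours of a (except b) hear the gist about b, and vice versa
        for (int x : nbr[a]) {
          if (x == b) continue;
          bucket(x, b).push(c_b, 0.0, intercept[x], t, false);
          ++total_gists;
        }
        for (int x : nbr[b]) {
          if (x == a) continue;
          bucket(x, a).push(c_a, 0.0, intercept[x], t, false);
          ++total_gists;
        }
      }
    }

    // periodic global sweep keeps dead traces from piling up in
    // never-queried buckets (identical outcomes: deletion is time-based)
    if (t % 200 == 0) {
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
          purge_bucket(bucket(i, j), t, forget_rate[i], min_strength[i]);
        }
      }
    }
  }

  // final purge so the reported trace counts reflect surviving traces
  std::vector<int> traces_alive(n, 0);
  for (int i = 0; i < n; ++i) {
    long long cnt = 0;
    for (int j = 0; j < n; ++j) {
      purge_bucket(bucket(i, j), n_rounds, forget_rate[i], min_strength[i]);
      cnt += bucket(i, j).size();
    }
    traces_alive[i] = (int)cnt;
  }

  DataFrame events = DataFrame::create(
    _["round"] = ev_round, _["id_a"] = ev_a, _["id_b"] = ev_b,
    _["c_a"] = ev_ca, _["c_b"] = ev_cb,
    _["payoff_a"] = ev_pa, _["payoff_b"] = ev_pb,
    _["emotion_a"] = ev_ea, _["emotion_b"] = ev_eb
  );

  return List::create(
    _["events"] = events,
    _["cumulative_payoff"] = payoff_cum,
    _["n_interactions"] = n_inter,
    _["n_active_rounds"] = n_active_rounds,
    _["final_mood"] = mood,
    _["final_beta"] = beta_t,
    _["traces_alive"] = traces_alive,
    _["total_gists"] = (double)total_gists
  );
}
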