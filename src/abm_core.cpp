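#include <Rcpp.h>
using namespace Rcpp;

// Finite-population simulator core. Semantics mirror the R-level operations
// (play_round / update_reputations / imitate_and_mutate): every agent plays
// everyone (including herself) once as donor per round, observers re-assess
// all views synchronously from one sampled interaction each, and propensity
// evolution uses Fermi pairwise comparison plus rare local mutation.
// Uses R's RNG throughout, so runs are reproducible via set.seed().

static inline int sample_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k < n ? k : n - 1;
}

// [[Rcpp::export(name = ".abm_run_cpp")]]
List abm_run_cpp(int N, int K, double qC, double qD,
                 int noi, int nos, IntegerVector obs_ind, IntegerVector obs_st,
                 IntegerVector group,
                 double b, double c, double eta, double ue, double ua,
                 double p0, int rounds, int pairs, double w,
                 double us, double sigma_p, int generations,
                 double games_norm, int sample_every, bool evolve,
                 bool record_rounds) {
  std::vector<double> p(N, p0);
  // views: observer-major storage
  std::vector<int> vi(noi * (size_t)N), vs(nos * (size_t)K);
  std::vector<int> vi_new(vi.size()), vs_new(vs.size());
  for (size_t i = 0; i < vi.size(); ++i) vi[i] = unif_rand() < 0.5 ? 1 : 0;
  for (size_t i = 0; i < vs.size(); ++i) vs[i] = unif_rand() < 0.5 ? 1 : 0;

  // members per group (contiguous blocks, but derive from `group` directly)
  std::vector< std::vector<int> > members(K);
  for (int i = 0; i < N; ++i) members[group[i]].push_back(i);

  std::vector<double> payoff(N);
  std::vector<int> act((size_t)N * N);

  int n_rec = generations / sample_every;
  IntegerVector rec_gen(n_rec);
  NumericVector rec_meanp(n_rec), rec_sdp(n_rec), rec_coop(n_rec),
      rec_pay(n_rec);
  NumericVector round_coop(record_rounds ? rounds : 0);
  int ir = 0;

  for (int gen = 1; gen <= generations; ++gen) {
    std::fill(payoff.begin(), payoff.end(), 0.0);
    long long coop_acts = 0;
    bool last_gen = (gen == generations);
    for (int r = 0; r < rounds; ++r) {
      long long coop_round = 0;
      // games: donor d -> recipient q
      for (int d = 0; d < N; ++d) {
        const int oi = obs_ind[d], os = obs_st[d];
        const double pd = p[d];
        double pay_d = 0.0;
        for (int q = 0; q < N; ++q) {
          bool use_ind = unif_rand() < 1.0 - pd;
          int view = use_ind ? vi[(size_t)oi * N + q]
                             : vs[(size_t)os * K + group[q]];
          bool coop = view && (unif_rand() >= ue);
          act[(size_t)d * N + q] = coop;
          if (coop) {
            pay_d -= c;
            payoff[q] += b;
            ++coop_round;
          }
          if (use_ind) pay_d -= eta;
        }
        payoff[d] += pay_d;
      }
      coop_acts += coop_round;
      if (record_rounds && last_gen)
        round_coop[r] = (double)coop_round / ((double)N * N);
      // individual assessments
      for (int o = 0; o < noi; ++o) {
        for (int d = 0; d < N; ++d) {
          int q = sample_int(N);
          int a = act[(size_t)d * N + q];
          int x = vi[(size_t)o * N + q];
          double pg = a ? (x ? 1.0 : qC) : (x ? 0.0 : qD);
          int assigned = unif_rand() < pg ? 1 : 0;
          if (unif_rand() < ua) assigned = 1 - assigned;
          vi_new[(size_t)o * N + d] = assigned;
        }
      }
      // stereotype assessments
      for (int o = 0; o < nos; ++o) {
        for (int k = 0; k < K; ++k) {
          int d = members[k][sample_int((int)members[k].size())];
          int q = sample_int(N);
          int a = act[(size_t)d * N + q];
          int x = vs[(size_t)o * K + group[q]];
          double pg = a ? (x ? 1.0 : qC) : (x ? 0.0 : qD);
          int assigned = unif_rand() < pg ? 1 : 0;
          if (unif_rand() < ua) assigned = 1 - assigned;
          vs_new[(size_t)o * K + k] = assigned;
        }
      }
      std::swap(vi, vi_new);
      std::swap(vs, vs_new);
    }
    // per-generation payoffs on the games_norm scale
    std::vector<double> pi(N);
    for (int i = 0; i < N; ++i)
      pi[i] = payoff[i] / ((double)rounds * N) * games_norm;
    double coop_frac = (double)coop_acts / ((double)rounds * N * N);

    if (evolve) {
      for (int t = 0; t < pairs; ++t) {
        int i = sample_int(N);
        int j = sample_int(N - 1);
        if (j >= i) ++j;
        double prob = 1.0 / (1.0 + std::exp(-w * (pi[i] - pi[j])));
        if (unif_rand() < prob) p[j] = p[i];
      }
      if (unif_rand() < us) {
        int m = sample_int(N);
        double np = p[m] + norm_rand() * sigma_p;
        p[m] = np < 0.0 ? 0.0 : (np > 1.0 ? 1.0 : np);
      }
    }
    if (gen % sample_every == 0 && ir < n_rec) {
      double mp = 0.0, mpay = 0.0;
      for (int i = 0; i < N; ++i) { mp += p[i]; mpay += pi[i]; }
      mp /= N; mpay /= N;
      double ss = 0.0;
      for (int i = 0; i < N; ++i) ss += (p[i] - mp) * (p[i] - mp);
      rec_gen[ir] = gen;
      rec_meanp[ir] = mp;
      rec_sdp[ir] = N > 1 ? std::sqrt(ss / (N - 1)) : 0.0;
      rec_coop[ir] = coop_frac;
      rec_pay[ir] = mpay;
      ++ir;
    }
  }
  DataFrame records = DataFrame::create(
      _["generation"] = rec_gen, _["mean_p"] = rec_meanp,
      _["sd_p"] = rec_sdp, _["coop"] = rec_coop,
      _["mean_payoff"] = rec_pay);
  return List::create(_["records"] = records, _["round_coop"] = round_coop);
}
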