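#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Structured Kingman coalescent over the three demographic scenarios
// (simple split / size change / admixture pulse) with piecewise-constant
// diploid sizes. Time runs backward in generations from the present.
// Populations: 0 = SALS, 1 = sampled NESP lineage, 2 = ancestral NESP,
// 3 = common ancestor. The unsampled ghost lineage receives no lineages
// and no migrants, so it is never represented.
//
// SNP ascertainment: a variable locus is observed with probability
// proportional to the total genealogy length, so each simulated genealogy
// emits a Poisson(lambda * L) number of loci, each carrying one mutation
// placed uniformly on the tree (every branch below the MRCA subtends a
// proper subset of samples, so every locus is variable in the pooled
// sample). This length-biased ascertainment is marginally exact for any
// lambda and reproduces the neutral SNP site-frequency spectrum
// (proportional to 1/i); lambda is set from a short pilot so that on
// average one locus is emitted per genealogy.
//
// Uses R's RNG throughout so set.seed() in R governs all draws.

struct Branch { uint64_t mask; double len; };

struct Event {
  double time;
  int type;  // 0 admix, 1 size->large, 2 size->small, 3 T2 merge, 4 T1 merge
};

static inline int pick_weighted(const double *w, int n, double total) {
  double u = unif_rand() * total;
  for (int i = 0; i < n; ++i) {
    u -= w[i];
    if (u <= 0) return i;
  }
  return n - 1;
}

struct Genealogy {
  std::vector<Branch> branches;
  double total_len;
};

// one structured genealogy; fills `out` with the 2n-2 branches below the MRCA
static void simulate_genealogy(int scenario, const double *par,
                               const std::vector<Event> &events,
                               int n1, int n2, Genealogy &out) {
  struct Lin { uint64_t mask; double birth; };
  std::vector<Lin> pops[4];
  out.branches.clear();
  for (int i = 0; i < 2 * n1; ++i) pops[0].push_back({1ULL << i, 0.0});
  for (int i = 0; i < 2 * n2; ++i) pops[1].push_back({1ULL << (2 * n1 + i), 0.0});
  double curN[4] = {par[4], par[5], par[3], par[2]};
  double t = 0.0;
  size_t ei = 0;
  int total = 2 * (n1 + n2);

  while (total > 1) {
    double rates[4], rate = 0.0;
    for (int p = 0; p < 4; ++p) {
      double k = (double)pops[p].size();
      rates[p] = k * (k - 1.0) / (4.0 * curN[p]);
      rate += rates[p];
    }
    double tnext = (ei < events.size()) ? events[ei].time : R_PosInf;
    double tc = (rate > 0) ? t + exp_rand() / rate : R_PosInf;
    if (tc < tnext) {
      t = tc;
      int p = pick_weighted(rates, 4, rate);
      int k = (int)pops[p].size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      Lin &a = pops[p][i], &b = pops[p][j];
      out.branches.push_back({a.mask, t - a.birth});
      out.branches.push_back({b.mask, t - b.birth});
      Lin merged = {a.mask | b.mask, t};
      pops[p][i] = merged;
      pops[p][j] = pops[p].back();
      pops[p].pop_back();
      --total;
    } else {
      t = tnext;
      switch (events[ei].type) {
      case 0: {  // admixture pulse: sampled-NESP lineage stays with prob r
        double r = par[11];
        std::vector<Lin> keep;
        for (auto &l : pops[1]) {
          if (unif_rand() < r) keep.push_back(l);
          else pops[0].push_back(l);
        }
        pops[1].swap(keep);
        break;
      }
      case 1: curN[1] = par[9]; break;
      case 2: curN[1] = par[8]; break;
      case 3:
        for (auto &l : pops[1]) pops[2].push_back(l);
        pops[1].clear();
        break;
      case 4:
        for (auto &l : pops[0]) pops[3].push_back(l);
        for (auto &l : pops[2]) pops[3].push_back(l);
        pops[0].clear(); pops[2].clear();
        break;
      }
      ++ei;
    }
  }
  double tot = 0.0;
  for (auto &b : out.branches) tot += b.len;
  out.total_len = tot;
}

static uint64_t place_mutation(const Genealogy &g) {
  double u = unif_rand() * g.total_len;
  for (auto &b : g.branches) {
    u -= b.len;
    if (u <= 0) return b.mask;
  }
  return g.branches.back().mask;
}

// par layout (times in generations, diploid effective sizes):
// 0 T1, 1 T2, 2 N_anc, 3 N_ancNESP, 4 N_SALS, 5 N_NESP,
// 6 T_rise, 7 T_fall, 8 N_small, 9 N_large, 10 T_admix, 11 r
// scenario: 1 simple split, 2 Ne change, 3 admixture
// [[Rcpp::export(name = ".sim_scenario_counts")]]
IntegerMatrix sim_scenario_counts(int scenario, NumericVector par,
                                  int n_loci, int n1, int n2) {
  const int ns = 2 * (n1 + n2);
  if (ns > 64) stop("at most 32 diploid samples in total are supported");
  const double T1 = par[0], T2 = par[1];
  if (!(T2 < T1)) stop("T2 must be smaller than T1");
  for (int i : {2, 3, 4, 5}) {
    if (par[i] <= 0) stop("population sizes must be positive");
  }
  if (scenario == 2 && (par[8] <= 0 || par[9] <= 0))
    stop("population sizes must be positive");

  std::vector<Event> events;
  if (scenario == 3) events.push_back({par[10], 0});
  if (scenario == 2) {
    events.push_back({par[7], 1});  // backward: size becomes N_large at T_fall
    events.push_back({par[6], 2});  // then N_small at T_rise
  }
  events.push_back({T2, 3});
  events.push_back({T1, 4});
  std::sort(events.begin(), events.end(),
            [](const Event &a, const Event &b) { return a.time < b.time; });

  IntegerMatrix out(n_loci, 4);
  RNGScope scope;
  Genealogy g;

  // pilot: mean total length sets the per-genealogy locus rate
  const int n_pilot = 16;
  double lbar = 0.0;
  for (int i = 0; i < n_pilot; ++i) {
    simulate_genealogy(scenario, REAL(par), events, n1, n2, g);
    lbar += g.total_len;
  }
  lbar /= n_pilot;
  double lambda = 1.0 / lbar;

  int loc = 0;
  while (loc < n_loci) {
    simulate_genealogy(scenario, REAL(par), events, n1, n2, g);
    int k = (int)R::rpois(lambda * g.total_len);
    for (int m = 0; m < k && loc < n_loci; ++m, ++loc) {
      uint64_t derived = place_mutation(g);
      int alt1 = 0, het1 = 0, alt2 = 0, het2 = 0;
      for (int i = 0; i < n1; ++i) {
        int d = (int)((derived >> (2 * i)) & 1ULL) +
                (int)((derived >> (2 * i + 1)) & 1ULL);
        alt1 += d; het1 += (d == 1);
      }
      for (int i = 0; i < n2; ++i) {
        int o = 2 * n1 + 2 * i;
        int d = (int)((derived >> o) & 1ULL) +
                (int)((derived >> (o + 1)) & 1ULL);
        alt2 += d; het2 += (d == 1);
      }
      out(loc, 0) = alt1; out(loc, 1) = het1;
      out(loc, 2) = alt2; out(loc, 3) = het2;
    }
  }
  colnames(out) = CharacterVector::create("alt1", "het1", "alt2", "het2");
  return out;
}

// Single panmictic population; derived-allele count of one mutation per
// locus under the same length-biased SNP ascertainment (site frequency
// spectrum check). A lower locus rate keeps emitted loci nearly
// independent.
// [[Rcpp::export(name = ".sim_single_pop_sfs")]]
IntegerVector sim_single_pop_sfs(int n_lineages, double N, int n_loci) {
  if (n_lineages < 2 || n_lineages > 64) stop("need 2..64 lineages");
  if (N <= 0) stop("population size must be positive");
  IntegerVector out(n_loci);
  RNGScope scope;

  // reuse the structured engine with a degenerate history: one panmictic
  // population of constant size (all samples in pop 0, merges in the past
  // never reached because the MRCA occurs first is not guaranteed, so the
  // merge times are set beyond any realistic TMRCA via a huge T1/T2)
  double par[12] = {0};
  par[0] = 1e18; par[1] = 0.5e18;
  par[2] = N; par[3] = N; par[4] = N; par[5] = N;
  std::vector<Event> events;
  events.push_back({par[1], 3});
  events.push_back({par[0], 4});

  int n1 = 0;  // all lineages enter as "pop 1" pairs? use pop 0 via n1
  // place all lineages in pop 0: n1 diploids = n_lineages/2 (n even required)
  if (n_lineages % 2 != 0) stop("n_lineages must be even");
  n1 = n_lineages / 2;

  Genealogy g;
  const int n_pilot = 16;
  double lbar = 0.0;
  for (int i = 0; i < n_pilot; ++i) {
    simulate_genealogy(1, par, events, n1, 0, g);
    lbar += g.total_len;
  }
  lbar /= n_pilot;
  double lambda = 0.4 / lbar;

  int loc = 0;
  while (loc < n_loci) {
    simulate_genealogy(1, par, events, n1, 0, g);
    int k = (int)R::rpois(lambda * g.total_len);
    for (int m = 0; m < k && loc < n_loci; ++m, ++loc) {
      uint64_t derived = place_mutation(g);
      int cnt = 0;
      for (int i = 0; i < n_lineages; ++i) cnt += (int)((derived >> i) & 1ULL);
      out[loc] = cnt;
    }
  }
  return out;
}
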