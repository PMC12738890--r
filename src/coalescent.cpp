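// Coalescent simulation of microsatellite (SSR) loci under multi-population
// demographic scenarios, with a generalized stepwise mutation model (GSM)
// plus single-nucleotide indels (SNI), and a fast summary-statistic path for
// ABC reference tables.

#include <Rcpp.h>
#include <climits>
#include <random>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Lineage {
  int node;
  int pop;  // 0-based
};

struct Ev {
  double time;
  int type;   // 1 merge, 2 admix, 3 resize
  int from;   // 0-based
  int to;     // 0-based
  int to2;    // 0-based (admix alternative target)
  double prob;  // admix: probability of moving to `to`
  double size;  // resize: new diploid size
};

// geometric step magnitude: P(|step| = k) = (1 - P) * P^(k-1), k >= 1
int gsm_magnitude(double P, std::mt19937_64 &rng) {
  if (P <= 0.0) return 1;
  std::geometric_distribution<int> g(1.0 - P);
  return g(rng) + 1;
}

}  // namespace

// Simulate `n_loci` independent SSR loci under a demographic scenario.
// sample_sizes: haploid sample count per group; pop_sizes: diploid N per
// group; events columns: time, type, from, to, to2, prob, size (1-based pops
// from R). Mutation vectors are per locus. Returns haploid allele sizes (nt)
// and per-locus TMRCA.
// [[Rcpp::export]]
List sim_coalescent_cpp(IntegerVector sample_sizes, NumericVector pop_sizes,
                        DataFrame events, NumericVector mu_l, NumericVector p_l,
                        NumericVector sni_l, int motif, int range_width,
                        int founder_repeat, int base_size, int seed) {
  const int n_groups = sample_sizes.size();
  const int n_loci = mu_l.size();
  int n_hap = 0;
  for (int g = 0; g < n_groups; ++g) n_hap += sample_sizes[g];
  if (n_hap < 2) stop("need at least 2 sampled haploids in total");

  std::vector<Ev> evs;
  {
    NumericVector t = events["time"];
    IntegerVector ty = events["type"], fr = events["from"], to = events["to"],
                  to2 = events["to2"];
    NumericVector pr = events["prob"], sz = events["size"];
    for (int i = 0; i < t.size(); ++i) {
      Ev e;
      e.time = t[i];
      e.type = ty[i];
      e.from = fr[i] - 1;
      e.to = to[i] - 1;
      e.to2 = to2[i] - 1;
      e.prob = pr[i];
      e.size = sz[i];
      evs.push_back(e);
    }
    std::stable_sort(evs.begin(), evs.end(),
                     [](const Ev &a, const Ev &b) { return a.time < b.time; });
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  IntegerMatrix alleles(n_hap, n_loci);
  NumericVector tmrca(n_loci);

  const int lo_rep = founder_repeat - range_width / 2 + 1;
  const int hi_rep = lo_rep + range_width - 1;

  for (int l = 0; l < n_loci; ++l) {
    // ---- genealogy -------------------------------------------------------
    const int n_nodes = 2 * n_hap - 1;
    std::vector<double> node_time(n_nodes, 0.0);
    std::vector<int> left(n_nodes, -1), right(n_nodes, -1);
    int next_node = n_hap;

    std::vector<Lineage> act;
    act.reserve(n_hap);
    {
      int idx = 0;
      for (int g = 0; g < n_groups; ++g)
        for (int i = 0; i < sample_sizes[g]; ++i) act.push_back({idx++, g});
    }
    std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
    double t = 0.0;
    size_t ev_idx = 0;

    while (act.size() > 1) {
      // per-pop coalescence rates
      std::vector<int> kpop(n_groups, 0);
      for (auto &ln : act) kpop[ln.pop]++;
      double total = 0.0;
      std::vector<double> rate(n_groups, 0.0);
      for (int g = 0; g < n_groups; ++g) {
        if (kpop[g] >= 2 && N[g] > 0)
          rate[g] = kpop[g] * (kpop[g] - 1) / 2.0 / (2.0 * N[g]);
        total += rate[g];
      }
      double next_ev = (ev_idx < evs.size()) ? evs[ev_idx].time : R_PosInf;
      double wait = R_PosInf;
      if (total > 0) {
        std::exponential_distribution<double> ex(total);
        wait = ex(rng);
      }
      if (t + wait < next_ev) {
        t += wait;
        // pick population proportional to rate, then a random pair in it
        double u = unif(rng) * total;
        int g = 0;
        for (; g < n_groups - 1; ++g) {
          if (u < rate[g]) break;
          u -= rate[g];
        }
        std::vector<int> members;
        for (size_t i = 0; i < act.size(); ++i)
          if (act[i].pop == g) members.push_back(static_cast<int>(i));
        int i1 = static_cast<int>(unif(rng) * members.size());
        int i2;
        do {
          i2 = static_cast<int>(unif(rng) * members.size());
        } while (i2 == i1);
        int a = members[i1], b = members[i2];
        int node = next_node++;
        node_time[node] = t;
        left[node] = act[a].node;
        right[node] = act[b].node;
        if (a > b) std::swap(a, b);
        act[a].node = node;
        act.erase(act.begin() + b);
      } else {
        if (!std::isfinite(next_ev))
          stop("lineages cannot all coalesce: no events left and no shared population");
        t = next_ev;
        const Ev &e = evs[ev_idx++];
        if (e.type == 1) {  // merge: lineages of `from` move to `to`
          for (auto &ln : act)
            if (ln.pop == e.from) ln.pop = e.to;
        } else if (e.type == 2) {  // admixture split (backwards in time)
          for (auto &ln : act)
            if (ln.pop == e.from) ln.pop = (unif(rng) < e.prob) ? e.to : e.to2;
        } else if (e.type == 3) {  // resize
          N[e.from] = e.size;
        }
      }
    }
    const int root = act[0].node;
    tmrca[l] = node_time[root];

    // ---- mutations down the tree ----------------------------------------
    std::vector<int> rep(n_nodes), off(n_nodes);
    std::vector<int> stack;
    rep[root] = founder_repeat;
    off[root] = 0;
    stack.push_back(root);
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      for (int child : {left[node], right[node]}) {
        if (child < 0) continue;
        double len = node_time[node] - node_time[child];
        int r = rep[node], o = off[node];
        // GSM repeat mutations, bounded ladder (redraw steps leaving range)
        int nmut = 0;
        if (mu_l[l] * len > 0) {
          std::poisson_distribution<int> pois(mu_l[l] * len);
          nmut = pois(rng);
        }
        for (int m = 0; m < nmut; ++m) {
          int tries = 0;
          while (true) {
            int mag = gsm_magnitude(p_l[l], rng);
            int step = (unif(rng) < 0.5) ? mag : -mag;
            int cand = r + step;
            if (cand >= lo_rep && cand <= hi_rep) {
              r = cand;
              break;
            }
            if (++tries > 1000) break;  // saturated at a boundary
          }
        }
        // SNI events: +/- 1 nt offsets
        if (sni_l[l] * len > 0) {
          std::poisson_distribution<int> pois_sni(sni_l[l] * len);
          int nsni = pois_sni(rng);
          for (int m = 0; m < nsni; ++m) o += (unif(rng) < 0.5) ? 1 : -1;
        }
        rep[child] = r;
        off[child] = o;
        stack.push_back(child);
      }
    }
    for (int i = 0; i < n_hap; ++i)
      alleles(i, l) = base_size + rep[i] * motif + off[i];
  }

  return List::create(_["alleles"] = alleles, _["tmrca"] = tmrca);
}

// ABC summary statistics from a haploid allele-size matrix. `group` is the
// 1-based group per haploid. Returns the fixed named vector:
// per group A (mean alleles/locus), H (genic diversity), V (allele-size
// variance in repeat units), M (Garza-Williamson); per group pair FST
// (pooled-pair HT/HS ratio of sums), DAS (1 - mean proportion of shared
// alleles, sum of min allele frequencies), dmu2 (squared difference of mean
// repeat size, averaged over loci).
// [[Rcpp::export]]
NumericVector sumstats_cpp(IntegerMatrix alleles, IntegerVector group,
                           int motif, int n_groups) {
  const int n_hap = alleles.nrow();
  const int n_loci = alleles.ncol();
  std::vector<std::vector<int>> members(n_groups);
  for (int i = 0; i < n_hap; ++i) members[group[i] - 1].push_back(i);

  const int n_pairs = n_groups * (n_groups - 1) / 2;
  NumericVector out(4 * n_groups + 3 * n_pairs);
  CharacterVector nm(out.size());

  // per-group per-locus allele frequency tables and moments
  std::vector<std::vector<std::map<int, int>>> counts(
      n_groups, std::vector<std::map<int, int>>(n_loci));
  std::vector<std::vector<double>> het(n_groups, std::vector<double>(n_loci));
  std::vector<std::vector<double>> mean_rep(n_groups, std::vector<double>(n_loci));

  for (int g = 0; g < n_groups; ++g) {
    double A = 0, H = 0, V = 0, M = 0;
    const int ng = static_cast<int>(members[g].size());
    for (int l = 0; l < n_loci; ++l) {
      auto &cnt = counts[g][l];
      double mean = 0;
      int amin = INT_MAX, amax = INT_MIN;
      for (int i : members[g]) {
        int a = alleles(i, l);
        cnt[a]++;
        mean += a;
        amin = std::min(amin, a);
        amax = std::max(amax, a);
      }
      mean /= ng;
      double ssq = 0, sum_p2 = 0;
      for (auto &kv : cnt) {
        double p = static_cast<double>(kv.second) / ng;
        sum_p2 += p * p;
        ssq += kv.second * std::pow(kv.first / static_cast<double>(motif) -
                                    mean / motif, 2.0);
      }
      double h = 1.0 - sum_p2;
      het[g][l] = h;
      mean_rep[g][l] = mean / motif;
      A += static_cast<double>(cnt.size());
      H += h;
      V += (ng > 1) ? ssq / (ng - 1) : 0.0;
      M += static_cast<double>(cnt.size()) / ((amax - amin) / motif + 1);
    }
    out[g] = A / n_loci;
    out[n_groups + g] = H / n_loci;
    out[2 * n_groups + g] = V / n_loci;
    out[3 * n_groups + g] = M / n_loci;
    nm[g] = "A." + std::to_string(g + 1);
    nm[n_groups + g] = "H." + std::to_string(g + 1);
    nm[2 * n_groups + g] = "V." + std::to_string(g + 1);
    nm[3 * n_groups + g] = "M." + std::to_string(g + 1);
  }

  int pair_idx = 0;
  for (int g1 = 0; g1 < n_groups - 1; ++g1) {
    for (int g2 = g1 + 1; g2 < n_groups; ++g2) {
      const int n1 = static_cast<int>(members[g1].size());
      const int n2 = static_cast<int>(members[g2].size());
      double sum_ht = 0, sum_hs = 0, das = 0, dmu2 = 0;
      for (int l = 0; l < n_loci; ++l) {
        // pooled HT from unweighted mean of the two allele-frequency vectors
        std::map<int, double> pooled;
        for (auto &kv : counts[g1][l])
          pooled[kv.first] += 0.5 * kv.second / n1;
        for (auto &kv : counts[g2][l])
          pooled[kv.first] += 0.5 * kv.second / n2;
        double sum_p2 = 0;
        for (auto &kv : pooled) sum_p2 += kv.second * kv.second;
        sum_ht += 1.0 - sum_p2;
        sum_hs += 0.5 * (het[g1][l] + het[g2][l]);
        dmu2 += std::pow(mean_rep[g1][l] - mean_rep[g2][l], 2.0);
        // shared-allele distance: 1 - sum of min allele frequencies
        double ps = 0;
        for (auto &kv : counts[g1][l]) {
          auto it = counts[g2][l].find(kv.first);
          if (it != counts[g2][l].end()) {
            ps += std::min(static_cast<double>(kv.second) / n1,
                           static_cast<double>(it->second) / n2);
          }
        }
        das += 1.0 - ps;
      }
      double fst = (sum_ht > 0) ? (sum_ht - sum_hs) / sum_ht : 0.0;
      int base = 4 * n_groups;
      std::string tag = std::to_string(g1 + 1) + "." + std::to_string(g2 + 1);
      out[base + pair_idx] = fst;
      out[base + n_pairs + pair_idx] = das / n_loci;
      out[base + 2 * n_pairs + pair_idx] = dmu2 / n_loci;
      nm[base + pair_idx] = "FST." + tag;
      nm[base + n_pairs + pair_idx] = "DAS." + tag;
      nm[base + 2 * n_pairs + pair_idx] = "dmu2." + tag;
      pair_idx++;
    }
  }
  out.attr("names") = nm;
  return out;
}
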