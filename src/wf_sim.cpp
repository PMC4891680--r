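// Two-population forward Wright-Fisher simulator under purifying selection.
//
// Sparse representation: each haplotype is the sorted vector of positions
// (0-based, finite sites on [0, L)) carrying the derived allele. Selection is
// multiplicative across sites with genotype fitness 1, 1+h*s, 1+s.
// Recombination draws Poisson(r*L) crossovers with uniform breakpoints.
// Sites fixed within a population are purged periodically; a fixed site is
// not segregating, so purging does not change any SNP or coSNP count.
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// bit-reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;
typedef std::vector<Hap> Pop;  // 2N haplotypes; individual i owns 2i, 2i+1

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static inline void add_mut(Hap &h, int pos) {
  Hap::iterator it = std::lower_bound(h.begin(), h.end(), pos);
  if (it == h.end() || *it != pos) h.insert(it, pos);
}

// one gamete from a parent's two haplotypes, with k crossovers
static void make_gamete(const Hap &a, const Hap &b, int k, int L, Hap &out) {
  out.clear();
  bool on_a = unif_rand() < 0.5;
  if (k == 0) {
    out = on_a ? a : b;
    return;
  }
  std::vector<int> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = rand_int(L);
  std::sort(bp.begin(), bp.end());
  bp.push_back(L);
  int prev = 0;
  for (size_t seg = 0; seg < bp.size(); ++seg) {
    int end = bp[seg];
    const Hap &s = on_a ? a : b;
    Hap::const_iterator it = std::lower_bound(s.begin(), s.end(), prev);
    while (it != s.end() && *it < end) out.push_back(*it++);
    prev = end;
    on_a = !on_a;
  }
}

// number of sites where both haplotypes carry the derived allele
static int count_hom(const Hap &a, const Hap &b) {
  int hom = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++hom; ++i; ++j; }
  }
  return hom;
}

static void purge_fixed(Pop &pop) {
  const int n = (int)pop.size();
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < n; ++i)
    for (size_t j = 0; j < pop[i].size(); ++j) cnt[pop[i][j]]++;
  std::vector<int> fixed;
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    if (it->second == n) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  Hap tmp;
  for (int i = 0; i < n; ++i) {
    tmp.clear();
    std::set_difference(pop[i].begin(), pop[i].end(),
                        fixed.begin(), fixed.end(), std::back_inserter(tmp));
    pop[i].swap(tmp);
  }
}

static void next_generation(Pop &pop, Pop &buf, int N, double s, double h,
                            double mu_total, double rL, int L,
                            const std::vector<double> &site_cum) {
  const int n2 = 2 * N;
  // parent sampling weights
  std::vector<double> cum;
  double tot = 0.0;
  if (s != 0.0) {
    cum.resize(N);
    const double log_het = std::log(1.0 + h * s);
    const double log_hom = std::log(1.0 + s);
    for (int i = 0; i < N; ++i) {
      const Hap &a = pop[2 * i], &b = pop[2 * i + 1];
      int hom = count_hom(a, b);
      int het = (int)a.size() + (int)b.size() - 2 * hom;
      tot += std::exp(het * log_het + hom * log_hom);
      cum[i] = tot;
    }
  }
  buf.resize(n2);
  // crossovers are Poisson-thinned over gametes: draw the generation total
  // once and scatter it, instead of one rpois call per gamete
  std::unordered_map<int, int> xo;
  if (rL > 0.0) {
    int total_x = (int)R::rpois(rL * n2);
    for (int x = 0; x < total_x; ++x) xo[rand_int(n2)]++;
  }
  for (int i = 0; i < N; ++i) {
    for (int par = 0; par < 2; ++par) {
      int p;
      if (s == 0.0) {
        p = rand_int(N);
      } else {
        double u = unif_rand() * tot;
        p = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (p >= N) p = N - 1;
      }
      int k = 0;
      if (!xo.empty()) {
        std::unordered_map<int, int>::iterator it = xo.find(2 * i + par);
        if (it != xo.end()) k = it->second;
      }
      make_gamete(pop[2 * p], pop[2 * p + 1], k, L, buf[2 * i + par]);
    }
  }
  // new mutations
  int nm = (mu_total > 0.0) ? (int)R::rpois(mu_total) : 0;
  for (int m = 0; m < nm; ++m) {
    int hap = rand_int(n2);
    int pos;
    if (site_cum.empty()) {
      pos = rand_int(L);
    } else {
      double u = unif_rand() * site_cum.back();
      pos = (int)(std::lower_bound(site_cum.begin(), site_cum.end(), u) -
                  site_cum.begin());
      if (pos >= L) pos = L - 1;
    }
    add_mut(buf[hap], pos);
  }
  pop.swap(buf);
}

// segregating positions among 2m sampled haplotypes (indices hap_idx)
static std::vector<int> seg_sites(const Pop &pop, const std::vector<int> &hap_idx) {
  std::unordered_map<int, int> cnt;
  const int n = (int)hap_idx.size();
  for (int i = 0; i < n; ++i) {
    const Hap &h = pop[hap_idx[i]];
    for (size_t j = 0; j < h.size(); ++j) cnt[h[j]]++;
  }
  std::vector<int> seg;
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    if (it->second > 0 && it->second < n) seg.push_back(it->first);
  std::sort(seg.begin(), seg.end());
  return seg;
}

// [[Rcpp::export(name = ".wf_sim_pair_cpp")]]
IntegerMatrix wf_sim_pair_cpp(int N, int L, double mu, double s, double h,
                              double r, int gens_post_split, int burn_in,
                              int sample_size, int iterations,
                              NumericVector site_rates) {
  if (N < 1 || L < 1 || iterations < 1) stop("invalid N/L/iterations");
  if (1.0 + s <= 0.0 || 1.0 + h * s <= 0.0)
    stop("genotype fitness <= 0; use a weaker selection coefficient");
  std::vector<double> site_cum;
  if (site_rates.size() > 0) {
    if ((int)site_rates.size() != L) stop("site_rates must have length L");
    site_cum.resize(L);
    double acc = 0.0;
    for (int i = 0; i < L; ++i) {
      if (site_rates[i] < 0) stop("site rates must be non-negative");
      acc += site_rates[i];
      site_cum[i] = acc;
    }
  }
  // mu is the mean per-base rate; a rate field only reshapes where mutations
  // land, not how many arrive, so the per-generation total is 2*N*mu*L
  const double mu_tot = 2.0 * N * mu * (double)L;
  const double rL = r * (double)L;
  const int n2 = 2 * N;
  const int m = (sample_size > 0 && sample_size < N) ? sample_size : N;

  IntegerMatrix out(iterations, 3);
  Pop anc(n2), buf(n2), popA, popB;
  for (int iter = 0; iter < iterations; ++iter) {
    checkUserInterrupt();
    for (int i = 0; i < n2; ++i) anc[i].clear();
    for (int g = 0; g < burn_in; ++g) {
      next_generation(anc, buf, N, s, h, mu_tot, rL, L, site_cum);
      if ((g & 31) == 31) purge_fixed(anc);
    }
    popA = anc;
    popB = anc;
    for (int g = 0; g < gens_post_split; ++g) {
      next_generation(popA, buf, N, s, h, mu_tot, rL, L, site_cum);
      next_generation(popB, buf, N, s, h, mu_tot, rL, L, site_cum);
      if ((g & 31) == 31) { purge_fixed(popA); purge_fixed(popB); }
    }
    // ascertainment sample: m individuals (2m haplotypes) per population
    std::vector<int> idx;
    if (m == N) {
      for (int i = 0; i < n2; ++i) idx.push_back(i);
    } else {
      std::vector<int> ind(N);
      for (int i = 0; i < N; ++i) ind[i] = i;
      for (int i = 0; i < m; ++i) {  // partial Fisher-Yates
        int j = i + rand_int(N - i);
        std::swap(ind[i], ind[j]);
      }
      for (int i = 0; i < m; ++i) {
        idx.push_back(2 * ind[i]);
        idx.push_back(2 * ind[i] + 1);
      }
    }
    std::vector<int> segA = seg_sites(popA, idx);
    std::vector<int> segB = seg_sites(popB, idx);
    std::vector<int> shared;
    std::set_intersection(segA.begin(), segA.end(), segB.begin(), segB.end(),
                          std::back_inserter(shared));
    out(iter, 0) = (int)segA.size();
    out(iter, 1) = (int)segB.size();
    out(iter, 2) = (int)shared.size();
  }
  return out;
}
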