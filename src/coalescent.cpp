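#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Per-site structured coalescent for a clean two-population split.
//
// Time runs backwards in units of 2N generations. Before `tsplit` the
// 2*n1 + 2*n2 haploid lineages coalesce only within their own deme at rate
// choose(k, 2); at `tsplit` the demes merge and the standard coalescent runs
// to the MRCA. Every emitted variant is biallelic with a single mutation
// whose carriers are the leaf set of one branch, chosen proportional to
// branch length. Two mutation-count models:
//
//   bernoulli (default): the site is variant with probability
//     min(1, theta/2 * total branch length). This is exactly unbiased for
//     pairwise differences (E[diff] = theta/2 * E[pair path length], hence
//     E[pi] = theta, E[dxy] = theta (1 + T)) because it never conditions
//     the genealogy on the mutation outcome.
//   poisson_redraw: M ~ Poisson(theta/2 * total branch length); sites with
//     M >= 2 are redrawn (genealogy and all). The rejection weights sites
//     by (1 + lambda) e^{-lambda}, down-weighting long genealogies, and
//     biases pi and dxy low by a few percent at theta ~ 0.005.
//
// Uses R's RNG so results are reproducible under set.seed(). Haplotype leaf
// sets are tracked as 64-bit masks, which caps the cohort at 64 haplotypes
// (32 diploids); the R wrapper enforces this.

namespace {

struct Lineage {
  uint64_t mask;
  double birth;
};

// Draw an unordered pair 0 <= i < j < k uniformly.
inline void draw_pair(int k, int &i, int &j) {
  i = (int)(unif_rand() * k);
  if (i >= k) i = k - 1;
  j = (int)(unif_rand() * (k - 1));
  if (j >= k - 1) j = k - 2;
  if (j >= i) ++j;
  if (i > j) std::swap(i, j);
}

} // namespace

// [[Rcpp::export(name = ".sim_split_sites_cpp")]]
List sim_split_sites_cpp(int n1, int n2, int L, double theta, double tsplit,
                         bool poisson_redraw = false, int max_redraws = 64) {
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1");
  if (n1 + n2 > 32) stop("at most 32 diploids (64 haplotypes) supported");
  if (L < 0) stop("L must be >= 0");
  if (theta < 0 || tsplit < 0) stop("theta and split time must be >= 0");

  const int H1 = 2 * n1, H2 = 2 * n2, H = H1 + H2;
  RNGScope scope;

  std::vector<int> var_site;
  std::vector<uint64_t> var_mask;
  std::vector<Lineage> d1, d2;
  std::vector<uint64_t> seg_mask;
  std::vector<double> seg_len;
  d1.reserve(H1); d2.reserve(H2);
  seg_mask.reserve(2 * H); seg_len.reserve(2 * H);

  for (int s = 0; s < L; ++s) {
    for (int attempt = 0;; ++attempt) {
      if (attempt > max_redraws)
        stop("site %d: exceeded %d redraws; theta too large for the "
             "single-mutation model", s + 1, max_redraws);
      d1.clear(); d2.clear(); seg_mask.clear(); seg_len.clear();
      for (int h = 0; h < H1; ++h) d1.push_back({uint64_t(1) << h, 0.0});
      for (int h = 0; h < H2; ++h) d2.push_back({uint64_t(1) << (H1 + h), 0.0});

      double t = 0.0;
      // phase 1: within-deme coalescence until the split time
      for (;;) {
        const double r1 = 0.5 * d1.size() * (d1.size() - 1.0);
        const double r2 = 0.5 * d2.size() * (d2.size() - 1.0);
        const double rate = r1 + r2;
        if (rate <= 0.0) { t = tsplit; break; }
        const double dt = exp_rand() / rate;
        if (t + dt >= tsplit) { t = tsplit; break; }
        t += dt;
        std::vector<Lineage> &d = (unif_rand() * rate < r1) ? d1 : d2;
        int i, j; draw_pair((int)d.size(), i, j);
        seg_mask.push_back(d[i].mask); seg_len.push_back(t - d[i].birth);
        seg_mask.push_back(d[j].mask); seg_len.push_back(t - d[j].birth);
        d[i].mask |= d[j].mask; d[i].birth = t;
        d[j] = d.back(); d.pop_back();
      }
      // phase 2: merged population to the MRCA
      std::vector<Lineage> &d = d1;
      d.insert(d.end(), d2.begin(), d2.end());
      while (d.size() > 1) {
        const double rate = 0.5 * d.size() * (d.size() - 1.0);
        t += exp_rand() / rate;
        int i, j; draw_pair((int)d.size(), i, j);
        seg_mask.push_back(d[i].mask); seg_len.push_back(t - d[i].birth);
        seg_mask.push_back(d[j].mask); seg_len.push_back(t - d[j].birth);
        d[i].mask |= d[j].mask; d[i].birth = t;
        d[j] = d.back(); d.pop_back();
      }

      double ttot = 0.0;
      for (double l : seg_len) ttot += l;
      const double lambda = 0.5 * theta * ttot;
      if (poisson_redraw) {
        const int m = (int)R::rpois(lambda);
        if (m == 0) break;          // invariant site
        if (m >= 2) continue;       // multi-hit: redraw the genealogy
      } else {
        if (unif_rand() >= std::min(1.0, lambda)) break;   // invariant
      }
      double u = unif_rand() * ttot;
      size_t pick = 0;
      for (; pick + 1 < seg_len.size(); ++pick) {
        u -= seg_len[pick];
        if (u <= 0.0) break;
      }
      var_site.push_back(s + 1);
      var_mask.push_back(seg_mask[pick]);
      break;
    }
  }

  const int nv = (int)var_site.size();
  IntegerVector site(var_site.begin(), var_site.end());
  LogicalMatrix derived(nv, H);
  for (int v = 0; v < nv; ++v)
    for (int h = 0; h < H; ++h)
      derived(v, h) = (var_mask[v] >> h) & 1u;
  return List::create(_["site"] = site, _["derived"] = derived);
}
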