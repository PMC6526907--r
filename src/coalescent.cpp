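#include <Rcpp.h>
using namespace Rcpp;

// Waiting time to the next coalescence among k lineages under a
// piecewise-constant diploid population size. Time is measured in
// generations backwards from the sampling point; epoch_start is ascending
// and begins at 0; the last epoch extends to infinity. Coalescence hazard
// for k lineages in an epoch of size N is k(k-1)/(4N) per generation.
static double next_coal_time(double t, int k,
                             const NumericVector &epoch_start,
                             const NumericVector &epoch_size) {
  double E = R::exp_rand();
  const double kk = (double)k * (k - 1.0);
  const int ne = epoch_start.size();
  int e = 0;
  while (e + 1 < ne && epoch_start[e + 1] <= t) ++e;
  double cur = t;
  for (;;) {
    double rate = kk / (4.0 * epoch_size[e]);
    double end = (e + 1 < ne) ? epoch_start[e + 1] : R_PosInf;
    if (!R_finite(end)) return cur + E / rate;
    double cap = (end - cur) * rate;
    if (E <= cap) return cur + E / rate;
    E -= cap;
    cur = end;
    ++e;
  }
}

// Simulate independent loci under the standard (Kingman) coalescent with
// infinite-sites mutation. Returns per-locus per-site pi (mean pairwise
// difference), and optionally the carrier sets of every segregating site
// so that sequences can be materialised in R. Uses R's RNG throughout so
// set.seed() controls reproducibility.
// [[Rcpp::export]]
List coalsim_cpp(int n_samples, int n_loci, int locus_len, double mu,
                 NumericVector epoch_start, NumericVector epoch_size,
                 bool return_sites) {
  if (n_samples < 2) stop("need at least 2 sampled chromosomes");
  NumericVector pi(n_loci);
  List sites(return_sites ? n_loci : 0);
  const double n = (double)n_samples;
  const double pair_denom = n * (n - 1.0) / 2.0;

  std::vector<std::vector<int> > desc(n_samples);
  std::vector<double> birth(n_samples);

  for (int l = 0; l < n_loci; ++l) {
    for (int i = 0; i < n_samples; ++i) {
      desc[i].assign(1, i + 1); // 1-based sample labels
      birth[i] = 0.0;
    }
    int k = n_samples;
    double t = 0.0, acc = 0.0;
    std::vector<std::vector<int> > carriers;

    while (k > 1) {
      t = next_coal_time(t, k, epoch_start, epoch_size);
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= a) ++b;
      if (a > b) std::swap(a, b);
      const int two[2] = {a, b};
      for (int s = 0; s < 2; ++s) {
        int idx = two[s];
        double len = t - birth[idx];
        int nm = (int)R::rpois(mu * (double)locus_len * len);
        if (nm > 0) {
          double d = (double)desc[idx].size();
          acc += (double)nm * d * (n - d) / pair_denom;
          if (return_sites)
            for (int m = 0; m < nm; ++m) carriers.push_back(desc[idx]);
        }
      }
      // merge lineage b into a; move last active lineage into slot b
      desc[a].insert(desc[a].end(), desc[b].begin(), desc[b].end());
      birth[a] = t;
      if (b != k - 1) {
        desc[b].swap(desc[k - 1]);
        birth[b] = birth[k - 1];
      }
      --k;
    }
    pi[l] = acc / (double)locus_len;
    if (return_sites) {
      List locus_sites(carriers.size());
      for (size_t m = 0; m < carriers.size(); ++m)
        locus_sites[m] = IntegerVector(carriers[m].begin(), carriers[m].end());
      sites[l] = locus_sites;
    }
  }
  return List::create(_["pi"] = pi, _["sites"] = sites);
}
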