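#include <Rcpp.h>
using namespace Rcpp;

// One discrete Wright-Fisher generation for a single chromosome.
// haps: 2N x L matrix of 0/1 alleles, rows 2k-2 and 2k-1 form diploid k.
// pos_m: locus positions in Morgans (nondecreasing). Each offspring gamete
// picks one diploid parent uniformly; the crossover count on the gamete is
// Poisson(map length) with uniform crossover positions (Haldane's model,
// no interference). Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_wf_generation(IntegerMatrix haps, NumericVector pos_m,
                                int n_off_haps) {
  int L = haps.ncol();
  int n_par = haps.nrow() / 2;
  if (n_par < 1) stop("need at least one diploid parent");
  double map_len = pos_m[L - 1] - pos_m[0];
  IntegerMatrix out(n_off_haps, L);
  std::vector<double> cx;
  for (int o = 0; o < n_off_haps; ++o) {
    int par = (int)(unif_rand() * n_par);
    if (par == n_par) par = n_par - 1;
    int h0 = 2 * par, h1 = 2 * par + 1;
    int cur = (unif_rand() < 0.5) ? h0 : h1;
    int k = (map_len > 0) ? (int)R::rpois(map_len) : 0;
    if (k == 0) {
      for (int l = 0; l < L; ++l) out(o, l) = haps(cur, l);
      continue;
    }
    cx.resize(k);
    for (int i = 0; i < k; ++i)
      cx[i] = pos_m[0] + unif_rand() * map_len;
    std::sort(cx.begin(), cx.end());
    int ci = 0;
    for (int l = 0; l < L; ++l) {
      while (ci < k && cx[ci] <= pos_m[l]) {
        cur = (cur == h0) ? h1 : h0;
        ++ci;
      }
      out(o, l) = haps(cur, l);
    }
  }
  return out;
}
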