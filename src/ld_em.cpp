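#include <Rcpp.h>
using namespace Rcpp;

// Two-locus EM for gamete (haplotype) frequencies from unphased diploid
// genotypes. Genotypes code copies of the B allele (0/1/2); the only
// ambiguous cell is the double heterozygote, which is split between the
// coupling (BB/aa) and repulsion (Ba/aB) phases at each E-step.
//
// Cell layout: n[i][j] = count of individuals with genotype i at locus 1
// and j at locus 2.

static double em_loglik(const double n[3][3], double f00, double f01,
                        double f10, double f11) {
  double P[3][3];
  P[0][0] = f00 * f00;
  P[0][1] = 2.0 * f00 * f01;
  P[0][2] = f01 * f01;
  P[1][0] = 2.0 * f00 * f10;
  P[1][1] = 2.0 * (f11 * f00 + f10 * f01);
  P[1][2] = 2.0 * f01 * f11;
  P[2][0] = f10 * f10;
  P[2][1] = 2.0 * f10 * f11;
  P[2][2] = f11 * f11;
  double ll = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (n[i][j] > 0) ll += n[i][j] * std::log(std::max(P[i][j], 1e-300));
  return ll;
}

// Core EM on a 3x3 genotype count table. Returns c(p11, p1, p2, loglik,
// iters, converged). Initialization at linkage equilibrium.
static void em_core(const double n[3][3], double tol, int max_iter,
                    double out[6]) {
  double T = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) T += n[i][j];
  T *= 2.0; // gametes

  // marginal B-allele frequencies
  double b1 = 2.0 * (n[2][0] + n[2][1] + n[2][2]) +
              (n[1][0] + n[1][1] + n[1][2]);
  double b2 = 2.0 * (n[0][2] + n[1][2] + n[2][2]) +
              (n[0][1] + n[1][1] + n[2][1]);
  double p1 = b1 / T, p2 = b2 / T;

  // unambiguous gamete contributions
  double k11 = 2.0 * n[2][2] + n[1][2] + n[2][1];
  double k00 = 2.0 * n[0][0] + n[0][1] + n[1][0];
  double k10 = 2.0 * n[2][0] + n[1][0] + n[2][1];
  double k01 = 2.0 * n[0][2] + n[0][1] + n[1][2];
  double dh = n[1][1];

  double f11 = p1 * p2, f10 = p1 * (1 - p2), f01 = (1 - p1) * p2,
         f00 = (1 - p1) * (1 - p2);
  int it = 0;
  bool conv = false;
  for (it = 0; it < max_iter; ++it) {
    double denom = f11 * f00 + f10 * f01;
    double x = (denom > 0) ? dh * (f11 * f00) / denom : dh * 0.5;
    double nf11 = (k11 + x) / T;
    double nf00 = (k00 + x) / T;
    double nf10 = (k10 + dh - x) / T;
    double nf01 = (k01 + dh - x) / T;
    double delta = std::fabs(nf11 - f11);
    f11 = nf11; f00 = nf00; f10 = nf10; f01 = nf01;
    if (delta < tol) { conv = true; ++it; break; }
  }
  out[0] = f11;
  out[1] = p1;
  out[2] = p2;
  out[3] = em_loglik(n, f00, f01, f10, f11);
  out[4] = (double)it;
  out[5] = conv ? 1.0 : 0.0;
}

static bool fill_table(const IntegerVector& gi, const IntegerVector& gj,
                       double n[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) n[i][j] = 0.0;
  int used = 0;
  for (int s = 0; s < gi.size(); ++s) {
    int a = gi[s], b = gj[s];
    if (a == NA_INTEGER || b == NA_INTEGER) continue;
    n[a][b] += 1.0;
    ++used;
  }
  return used > 0;
}

// [[Rcpp::export]]
List cpp_em_pair(IntegerVector gi, IntegerVector gj, double tol,
                 int max_iter) {
  double n[3][3];
  if (!fill_table(gi, gj, n))
    stop("no jointly non-missing genotypes for this pair");
  double out[6];
  em_core(n, tol, max_iter, out);
  return List::create(_["p_ab"] = out[0], _["p_i"] = out[1],
                      _["p_j"] = out[2], _["loglik"] = out[3],
                      _["iterations"] = (int)out[4],
                      _["converged"] = out[5] > 0.5);
}

// All intra-chromosome pairs within max_bp and max_gap index distance.
// Returns dist (bp) and r2; monomorphic members make LD undefined and the
// pair is skipped (count returned in attribute "n_skipped").
// [[Rcpp::export]]
List cpp_pairwise_ld(IntegerMatrix calls, IntegerVector chrom,
                     IntegerVector pos, double max_bp, int max_gap,
                     double tol, int max_iter) {
  int m = calls.ncol();
  std::vector<double> dist, r2;
  long skipped = 0;
  double n[3][3], out[6];
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m && b - a <= max_gap; ++b) {
      if (chrom[b] != chrom[a]) break; // variants sorted by (chrom, pos)
      double d = (double)pos[b] - (double)pos[a];
      if (d > max_bp) break;
      IntegerVector gi = calls(_, a), gj = calls(_, b);
      if (!fill_table(gi, gj, n)) { ++skipped; continue; }
      em_core(n, tol, max_iter, out);
      double p1 = out[1], p2 = out[2];
      if (p1 <= 0.0 || p1 >= 1.0 || p2 <= 0.0 || p2 >= 1.0) {
        ++skipped;
        continue;
      }
      double D = out[0] - p1 * p2;
      dist.push_back(d);
      r2.push_back(D * D / (p1 * (1 - p1) * p2 * (1 - p2)));
    }
  }
  List res = List::create(_["dist_bp"] = wrap(dist), _["r2"] = wrap(r2));
  res.attr("n_skipped") = (double)skipped;
  return res;
}
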