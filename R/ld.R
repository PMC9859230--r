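#' Squared allelic correlation from haplotype frequencies
#'
#' The LD statistic r2 = (p_ab - p_i p_j)^2 / (p_i (1 - p_i) p_j (1 - p_j)),
#' where p_ab is the frequency of the gamete carrying the B allele at both
#' loci and p_i, p_j are the marginal B-allele frequencies.
#'
#' @param p_ab joint (haplotype) frequency of the B-B gamete.
#' @param p_i,p_j marginal B-allele frequencies, both strictly in (0, 1).
#' @return r2 in \[0, 1\].
#' @export
r2_from_freqs <- function(p_ab, p_i, p_j) {
  if (p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1)
    stop("LD undefined at a monomorphic locus")
  d <- p_ab - p_i * p_j
  d^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood gamete frequencies for a pair of biallelic loci
#' under random union of gametes. All genotype configurations except the
#' double heterozygote determine their gametes; the EM iteration splits
#' the double heterozygotes between coupling and repulsion phase.
#' Initialisation is at linkage equilibrium, making the result
#' deterministic given the data.
#'
#' @param calls_i,calls_j genotype vectors (0/1/2 copies of the B allele).
#' @param tol convergence threshold on the change in `p_ab`.
#' @param max_iter iteration cap; non-convergence is flagged, the last
#'   iterate is returned.
#' @return List: `p_ab`, `p_i`, `p_j`, `loglik`, `iterations`,
#'   `converged`, and `r2` (NA if either locus is monomorphic).
#' @export
em_haplotype_freqs <- function(calls_i, calls_j, tol = 1e-10,
                               max_iter = 1000L) {
  res <- cpp_em_pair(as.integer(calls_i), as.integer(calls_j), tol,
                     as.integer(max_iter))
  res$r2 <- if (res$p_i > 0 && res$p_i < 1 && res$p_j > 0 && res$p_j < 1)
    r2_from_freqs(res$p_ab, res$p_i, res$p_j) else NA_real_
  res
}

#' r2 for one pair directly from phased haplotypes
#'
#' Direct gamete counting; used as the phased-truth reference against the
#' EM genotype-based estimate.
#'
#' @param hap_i,hap_j 0/1 allele vectors over the same gametes.
#' @return r2, or NA if either locus is monomorphic.
#' @export
r2_phased <- function(hap_i, hap_j) {
  p_i <- mean(hap_i)
  p_j <- mean(hap_j)
  if (p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1) return(NA_real_)
  r2_from_freqs(mean(hap_i == 1 & hap_j == 1), p_i, p_j)
}

#' All within-window marker pairs with their r2
#'
#' Enumerates every intra-chromosome pair of markers whose physical
#' distance is at most `max_bp` and whose index separation is at most
#' `max_snp_gap`, computing r2 via the two-locus EM. Pairs with a
#' monomorphic member have undefined LD and are skipped (counted in the
#' `n_skipped` attribute).
#'
#' @param g a [geno_matrix] (complete calls; impute first).
#' @param max_bp distance cap in bp (default 1 Mb).
#' @param max_snp_gap index-separation cap (default 99,999).
#' @param tol,max_iter EM controls, see [em_haplotype_freqs()].
#' @return Data frame with columns `dist_bp`, `r2`; attribute
#'   `n_skipped`.
#' @export
pairwise_ld_window <- function(g, max_bp = 1e6, max_snp_gap = 99999L,
                               tol = 1e-10, max_iter = 1000L) {
  res <- cpp_pairwise_ld(g$calls, as.integer(g$variants$chrom),
                         as.integer(g$variants$pos), max_bp,
                         as.integer(max_snp_gap), tol,
                         as.integer(max_iter))
  out <- data.frame(dist_bp = res$dist_bp, r2 = res$r2)
  attr(out, "n_skipped") <- attr(res, "n_skipped")
  out
}

#' Binned LD-decay curve
#'
#' Arithmetic mean of pair r2 per half-open physical-distance bin
#' \[k w, (k+1) w). Empty bins carry `n_pairs = 0` and `mean_r2 = NA`.
#'
#' @param pairs data frame from [pairwise_ld_window()].
#' @param bin_width bin width in bp (default 2,500).
#' @param max_dist curve extent in bp (default 500 kb).
#' @return Data frame with `lo`, `hi`, `n_pairs`, `mean_r2`.
#' @export
decay_bins <- function(pairs, bin_width = 2500, max_dist = 500000) {
  k <- ceiling(max_dist / bin_width)
  lo <- (seq_len(k) - 1) * bin_width
  idx <- floor(pairs$dist_bp / bin_width) + 1
  keep <- idx >= 1 & idx <= k
  n_pairs <- tabulate(idx[keep], nbins = k)
  sums <- rep(0, k)
  agg <- tapply(pairs$r2[keep], idx[keep], sum)
  sums[as.integer(names(agg))] <- agg
  data.frame(lo = lo, hi = lo + bin_width, n_pairs = n_pairs,
             mean_r2 = ifelse(n_pairs > 0, sums / n_pairs, NA_real_))
}

#' Average r2 over a distance range
#'
#' Two conventions are offered: `pair` weights every marker pair in the
#' range equally; `bin` first averages within distance bins and then
#' averages the non-empty bin means. The two differ when pair counts vary
#' across bins.
#'
#' @param pairs data frame from [pairwise_ld_window()].
#' @param lo,hi half-open distance range in bp.
#' @param method `"pair"` or `"bin"`.
#' @param bin_width bin width for `method = "bin"`.
#' @return Mean r2 (NA if no pairs fall in the range).
#' @export
mean_r2_range <- function(pairs, lo = 0, hi = 50000,
                          method = c("pair", "bin"), bin_width = 2500) {
  method <- match.arg(method)
  inr <- pairs$dist_bp >= lo & pairs$dist_bp < hi
  if (!any(inr)) return(NA_real_)
  if (method == "pair") return(mean(pairs$r2[inr]))
  b <- decay_bins(pairs[inr, , drop = FALSE], bin_width = bin_width,
                  max_dist = hi)
  b <- b[b$lo >= lo & b$n_pairs > 0, , drop = FALSE]
  mean(b$mean_r2)
}
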