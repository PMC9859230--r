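# Small builders and independent oracles shared across test files.

# geno_matrix from a bare call matrix (one chromosome, 10 kb spacing)
make_geno <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  variants <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = pos, allele_a = "A", allele_b = "B",
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("s", seq_len(nrow(calls))),
                        stringsAsFactors = FALSE)
  geno_matrix(calls, variants, samples)
}

# Independent HWE oracle: enumerate every heterozygote count compatible
# with the allele counts and accumulate multinomial probabilities with
# plain factorials (no shared code with hwe_exact_test).
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nB <- 2 * n_BB + n_AB
  if (nB == 0 || nB == 2 * n) return(1)
  hs <- seq(nB %% 2, min(nB, 2 * n - nB), by = 2)
  pr <- vapply(hs, function(h) {
    bb <- (nB - h) / 2
    aa <- n - bb - h
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
          h * log(2) + lgamma(nB + 1) + lgamma(2 * n - nB + 1) -
          lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_AB]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Reference two-locus EM in plain R, tracking the log-likelihood path so
# monotonicity can be asserted; independent of the C++ kernel.
em_reference <- function(gi, gj, tol = 1e-10, max_iter = 1000) {
  tab <- matrix(0, 3, 3)
  for (s in seq_along(gi)) tab[gi[s] + 1, gj[s] + 1] <- tab[gi[s] + 1, gj[s] + 1] + 1
  T <- 2 * sum(tab)
  p1 <- (sum(tab[2, ]) + 2 * sum(tab[3, ])) / T
  p2 <- (sum(tab[, 2]) + 2 * sum(tab[, 3])) / T
  k11 <- 2 * tab[3, 3] + tab[2, 3] + tab[3, 2]
  k00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  k10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
  k01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  dh <- tab[2, 2]
  f <- c(f00 = (1 - p1) * (1 - p2), f01 = (1 - p1) * p2,
         f10 = p1 * (1 - p2), f11 = p1 * p2)
  ll_of <- function(f) {
    P <- matrix(0, 3, 3)
    P[1, 1] <- f["f00"]^2; P[1, 2] <- 2 * f["f00"] * f["f01"]
    P[1, 3] <- f["f01"]^2; P[2, 1] <- 2 * f["f00"] * f["f10"]
    P[2, 2] <- 2 * (f["f11"] * f["f00"] + f["f10"] * f["f01"])
    P[2, 3] <- 2 * f["f01"] * f["f11"]; P[3, 1] <- f["f10"]^2
    P[3, 2] <- 2 * f["f10"] * f["f11"]; P[3, 3] <- f["f11"]^2
    sum(tab[tab > 0] * log(pmax(P[tab > 0], 1e-300)))
  }
  ll_path <- ll_of(f)
  for (it in seq_len(max_iter)) {
    den <- unname(f["f11"] * f["f00"] + f["f10"] * f["f01"])
    x <- unname(if (den > 0) dh * f["f11"] * f["f00"] / den else dh / 2)
    fn <- c(f00 = (k00 + x) / T, f01 = (k01 + dh - x) / T,
            f10 = (k10 + dh - x) / T, f11 = (k11 + x) / T)
    delta <- abs(fn["f11"] - f["f11"])
    f <- fn
    ll_path <- c(ll_path, ll_of(f))
    if (delta < tol) break
  }
  list(p_ab = unname(f["f11"]), p_i = p1, p_j = p2, ll_path = ll_path)
}

# Collapse a hap_set to genotypes and keep per-chromosome phased columns
hap_columns <- function(haps, chrom) haps$chroms[[chrom]]$haps
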