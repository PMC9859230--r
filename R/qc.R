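#' Quality-control configuration
#'
#' Thresholds for the marker/sample QC battery. Defaults follow standard
#' SNP-array practice for livestock panels: call rate >= 90%, MAF >= 1%,
#' Hardy-Weinberg exact p >= 1e-6, sample missingness <= 5%, and removal
#' of one member of any near-duplicate pair with r2 > 0.998.
#'
#' @param min_call_rate minimum per-variant call rate.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg exact-test significance cutoff.
#' @param max_sample_missingness maximum per-sample missing fraction.
#' @param dedup_r2 r2 threshold above which a pair is treated as duplicate.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_call_rate = 0.90, min_maf = 0.01,
                      hwe_alpha = 1e-6, max_sample_missingness = 0.05,
                      dedup_r2 = 0.998) {
  cfg <- list(min_call_rate = min_call_rate, min_maf = min_maf,
              hwe_alpha = hwe_alpha,
              max_sample_missingness = max_sample_missingness,
              dedup_r2 = dedup_r2)
  stopifnot(all(unlist(cfg) > 0), all(unlist(cfg) <= 1))
  structure(cfg, class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions by full enumeration
#' of heterozygote counts conditional on the allele counts. The p-value is
#' the sum of probabilities of all outcomes no more probable than the
#' observed one (plain exact test, no mid-p adjustment).
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0)
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("all genotype counts are zero")
  nB <- 2 * n_BB + n_AB
  nA <- 2 * n - nB
  if (nB == 0 || nA == 0) return(1) # monomorphic: single possible outcome
  # possible het counts share the parity of nB
  h <- seq(nB %% 2, min(nA, nB), by = 2)
  # P(h) = 2^h n! nA! nB! / ( ((nA-h)/2)! ((nB-h)/2)! h! (2n)! )
  logp <- h * log(2) + lfactorial(n) + lfactorial(nA) + lfactorial(nB) -
    lfactorial((nA - h) / 2) - lfactorial((nB - h) / 2) - lfactorial(h) -
    lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[h == n_AB]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

hwe_p_all <- function(g) {
  vapply(seq_len(n_variants(g)), function(j) {
    x <- g$calls[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
}

qc_report <- function(axis, rule, n_removed, n_before) {
  data.frame(axis = axis, rule = rule, n_removed = n_removed,
             n_before = n_before, n_after = n_before - n_removed,
             stringsAsFactors = FALSE)
}

#' Remove samples with excess missing genotypes
#'
#' Samples whose missing-call fraction exceeds the threshold are excluded.
#' Missingness is computed on the matrix as given, before any variant
#' filtering.
#'
#' @param g a [geno_matrix].
#' @param cfg a [qc_config()].
#' @return List with the filtered `geno_matrix` and a `report` data frame.
#' @export
filter_samples <- function(g, cfg = qc_config()) {
  miss <- sample_missingness(g)
  drop <- miss > cfg$max_sample_missingness
  if (all(drop)) stop("all samples removed by the missingness filter")
  rep <- qc_report("sample", "missingness", sum(drop), n_samples(g))
  rep$removed_ids <- paste(g$samples$id[drop], collapse = ",")
  list(geno = subset_geno(g, samples = which(!drop)), report = rep)
}

#' Remove variants failing marker-level QC
#'
#' Applies, in order: call rate, minor allele frequency, Hardy-Weinberg
#' exact test, and a final monomorphic check. Each variant is attributed
#' to the first rule it fails; the report itemises removals per rule.
#'
#' @param g a [geno_matrix].
#' @param cfg a [qc_config()].
#' @return List with the filtered `geno_matrix`, a per-rule `report`, and
#'   a `rule` vector naming the failed rule (or `"pass"`) per input
#'   variant.
#' @export
filter_variants <- function(g, cfg = qc_config()) {
  m0 <- n_variants(g)
  cr <- variant_call_rate(g)
  maf <- variant_maf(g)
  rule <- rep("pass", m0)
  rule[maf == 0] <- "monomorphic"
  rule[maf > 0 & maf < cfg$min_maf] <- "low_maf"
  # HWE only for variants still alive after the cheaper rules
  alive <- rule == "pass"
  hw <- rep(NA_real_, m0)
  hw[alive] <- hwe_p_all(subset_geno(g, variants = which(alive)))
  rule[alive & hw < cfg$hwe_alpha] <- "hwe"
  rule[cr < cfg$min_call_rate] <- "call_rate" # applied first: overrides
  rep <- do.call(rbind, lapply(
    c("call_rate", "low_maf", "hwe", "monomorphic"),
    function(r) qc_report("variant", r, sum(rule == r), m0)))
  # n_before per row reflects sequential application
  seq_removed <- cumsum(c(0, rep$n_removed[-nrow(rep)]))
  rep$n_before <- m0 - seq_removed
  rep$n_after <- rep$n_before - rep$n_removed
  list(geno = subset_geno(g, variants = which(rule == "pass")),
       report = rep, rule = rule)
}

# composite (genotype-correlation) r2 between two call vectors
r2_composite <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Remove near-duplicate markers by LD
#'
#' Within each chromosome, scanning in position order, each variant is
#' compared against the last retained variant; if their genotype r2
#' exceeds the threshold the right-hand (higher-position) member is
#' dropped, so the lower-position member of a duplicate run survives.
#'
#' @param g a [geno_matrix] with variants sorted by (chrom, pos).
#' @param cfg a [qc_config()].
#' @return List with the filtered `geno_matrix` and a `report`.
#' @export
dedup_ld_filter <- function(g, cfg = qc_config()) {
  m <- n_variants(g)
  keep <- rep(TRUE, m)
  last_kept <- -1L
  last_chrom <- -1L
  for (j in seq_len(m)) {
    ch <- g$variants$chrom[j]
    if (ch != last_chrom) {
      last_chrom <- ch
      last_kept <- j
      next
    }
    r2 <- r2_composite(g$calls[, last_kept], g$calls[, j])
    if (!is.na(r2) && r2 > cfg$dedup_r2) {
      keep[j] <- FALSE
    } else {
      last_kept <- j
    }
  }
  rep <- qc_report("variant", "dedup_ld", sum(!keep), m)
  list(geno = subset_geno(g, variants = which(keep)), report = rep)
}

#' Impute missing genotypes from allele frequencies
#'
#' Each missing call is replaced by an independent draw from
#' Binomial(2, f) with f the variant's observed B-allele frequency. A
#' deliberately simple, seeded imputer: per-variant missingness after QC
#' is low, and downstream statistics are insensitive to it (see the
#' mask-and-recover test). Non-missing calls are never altered.
#'
#' @param g a post-QC [geno_matrix].
#' @param seed integer RNG seed.
#' @return A `geno_matrix` with no missing calls.
#' @export
impute_missing <- function(g, seed = 1L) {
  if (!anyNA(g$calls)) return(g)
  f <- allele_frequencies(g)
  calls <- g$calls
  set.seed(seed)
  for (j in which(colSums(is.na(calls)) > 0)) {
    miss <- which(is.na(calls[, j]))
    calls[miss, j] <- rbinom(length(miss), 2L, f[j])
  }
  geno_matrix(calls, g$variants, g$samples)
}

#' Minor-allele-frequency spectrum
#'
#' Counts and proportions of retained markers in the five conventional
#' MAF categories \[0.05, 0.1), \[0.1, 0.2), \[0.2, 0.3), \[0.3, 0.4),
#' \[0.4, 0.5\], plus an extra unplotted category for markers with
#' MAF below 0.05 that survive QC. Also reports the mean MAF and the
#' proportions of markers above 0.1 and above 0.2.
#'
#' @param g a post-QC [geno_matrix].
#' @return A `maf_spectrum` list with `bins` (data frame), `mean_maf`,
#'   `prop_above_0.1`, `prop_above_0.2`.
#' @export
maf_spectrum <- function(g) {
  maf <- variant_maf(g)
  edges <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  labs <- c("[0.05,0.1)", "[0.1,0.2)", "[0.2,0.3)", "[0.3,0.4)", "[0.4,0.5]")
  counts <- integer(5)
  for (k in 1:4) counts[k] <- sum(maf >= edges[k] & maf < edges[k + 1])
  counts[5] <- sum(maf >= 0.4 & maf <= 0.5)
  below <- sum(maf < 0.05)
  bins <- data.frame(bin = labs, lo = edges[1:5], hi = edges[2:6],
                     count = counts, proportion = counts / length(maf))
  structure(list(bins = bins, n_below_0.05 = below,
                 mean_maf = mean(maf),
                 prop_above_0.1 = mean(maf >= 0.1),
                 prop_above_0.2 = mean(maf >= 0.2),
                 n_markers = length(maf)),
            class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  cat(sprintf("MAF spectrum over %d markers (mean MAF %.3f)\n",
              x$n_markers, x$mean_maf))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Run the full QC battery
#'
#' Sample missingness, then variant call rate / MAF / HWE / monomorphic,
#' then near-duplicate LD pruning, then binomial imputation of remaining
#' missing calls. Per-chromosome retained-marker counts and mean spacing
#' are attached to the report.
#'
#' @param g a [geno_matrix].
#' @param cfg a [qc_config()].
#' @param seed seed for the imputation draws.
#' @param impute impute remaining missing calls (default TRUE).
#' @return List: `geno` (clean matrix), `report` (rule table),
#'   `chrom_summary` (per-chromosome counts and mean spacing in bp).
#' @export
run_qc <- function(g, cfg = qc_config(), seed = 1L, impute = TRUE) {
  s <- filter_samples(g, cfg)
  v <- filter_variants(s$geno, cfg)
  d <- dedup_ld_filter(v$geno, cfg)
  out <- d$geno
  if (impute) out <- impute_missing(out, seed = seed)
  report <- rbind(s$report[, names(d$report)], v$report, d$report)
  vv <- out$variants
  chrom_summary <- do.call(rbind, lapply(split(vv$pos, vv$chrom), function(p) {
    data.frame(n_markers = length(p),
               mean_spacing_bp = if (length(p) > 1) mean(diff(sort(p))) else NA)
  }))
  chrom_summary$chrom <- as.integer(rownames(chrom_summary))
  list(geno = out, report = report, chrom_summary = chrom_summary)
}
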