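test_that("HWE exact test matches the enumeration oracle for totals <= 50", {
  cases <- expand.grid(aa = c(0, 1, 3, 10, 20), ab = c(0, 2, 5, 12),
                       bb = c(0, 1, 4, 9))
  cases <- cases[rowSums(cases) >= 1 & rowSums(cases) <= 50, ]
  for (i in seq_len(nrow(cases))) {
    p1 <- hwe_exact_test(cases$aa[i], cases$ab[i], cases$bb[i])
    p2 <- hwe_oracle(cases$aa[i], cases$ab[i], cases$bb[i])
    expect_equal(p1, p2, tolerance = 1e-12,
                 info = paste(cases[i, ], collapse = "/"))
  }
})

test_that("HWE edge cases: monomorphic, tiny counts, balanced proportions", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  # 2 A + 2 B alleles in 2 genotypes: only het counts 0 and 2 possible
  expect_equal(hwe_exact_test(0, 2, 0), hwe_oracle(0, 2, 0))
  # observed het count is the modal outcome -> p = 1 region
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("variant filter removes and attributes violations correctly", {
  # 85% call rate variant (rule: call_rate)
  calls <- matrix(1L, 20, 4)
  calls[, 1] <- rep(c(0L, 1L, 2L, 1L), 5)
  calls[1:4, 1] <- NA            # 80% call rate
  calls[, 2] <- 0L               # monomorphic
  calls[, 3] <- rep(c(0L, 1L), 10)
  calls[, 4] <- rep(c(0L, 2L), 10) # no hets, HWE-violating at n=20
  g <- make_geno(calls)
  fv <- filter_variants(g, qc_config(hwe_alpha = 1e-3))
  expect_equal(fv$rule, c("call_rate", "monomorphic", "pass", "hwe"))
  expect_equal(ncol(fv$geno$calls), 1L)
  # conservation: removed + retained = input
  expect_equal(sum(fv$report$n_removed) + ncol(fv$geno$calls), 4L)
})

test_that("variant filtering is idempotent", {
  set.seed(33)
  g <- sim_unlinked_genotypes(60, 80, seed = 33)
  g$calls[sample(length(g$calls), 200)] <- NA_integer_
  f1 <- filter_variants(g, qc_config())
  f2 <- filter_variants(f1$geno, qc_config())
  expect_equal(f2$geno$calls, f1$geno$calls)
  expect_equal(sum(f2$report$n_removed), 0)
})

test_that("sample filter drops exactly the high-missingness samples", {
  calls <- matrix(0:2, 10, 30)
  calls[1, 1:3] <- NA  # 10% missing -> removed
  calls[2, 1] <- NA    # 3.3% -> retained
  g <- make_geno(calls)
  fs <- filter_samples(g, qc_config())
  expect_equal(nrow(fs$geno$calls), 9L)
  expect_equal(fs$report$n_removed, 1L)
  g_all_bad <- make_geno(matrix(NA_integer_, 3, 10))
  expect_error(filter_samples(g_all_bad), "all samples")
})

test_that("dedup keeps the lower-position member of duplicate runs", {
  set.seed(44)
  x <- sample(0:2, 40, replace = TRUE)
  y <- sample(0:2, 40, replace = TRUE)
  # identical pair: second removed
  g <- make_geno(cbind(x, x, y))
  dd <- dedup_ld_filter(g, qc_config())
  expect_equal(dd$geno$variants$id, c("v1", "v3"))
  # independent pair: both kept
  g2 <- make_geno(cbind(x, y))
  expect_equal(ncol(dedup_ld_filter(g2)$geno$calls), 2L)
  # mutually-duplicated triplet: one survivor (the leftmost)
  g3 <- make_geno(cbind(x, x, x))
  expect_equal(dedup_ld_filter(g3)$geno$variants$id, "v1")
  # chromosomes are independent scans
  g4 <- make_geno(cbind(x, x), chrom = c(1L, 2L), pos = c(100L, 100L))
  expect_equal(ncol(dedup_ld_filter(g4)$geno$calls), 2L)
})

test_that("dedup output has no adjacent within-chromosome pair above threshold", {
  set.seed(45)
  base <- sample(0:2, 50, replace = TRUE)
  cols <- sapply(1:12, function(i) {
    z <- base
    flip <- sample(50, sample(0:6, 1))
    z[flip] <- sample(0:2, length(flip), replace = TRUE)
    z
  })
  g <- make_geno(cols)
  dd <- dedup_ld_filter(g, qc_config())
  cl <- dd$geno$calls
  if (ncol(cl) > 1) {
    for (j in 2:ncol(cl)) {
      r2 <- popgenchip:::r2_composite(cl[, j - 1], cl[, j])
      expect_lte(r2, 0.998)
    }
  }
})

test_that("imputation fills only missing calls, binomially at f-hat", {
  g <- sim_unlinked_genotypes(50, 20, seed = 55)
  expect_identical(impute_missing(g, 1)$calls, g$calls)
  # f-hat = 0 forces imputed 0
  calls <- cbind(c(0L, 0L, 0L, NA))
  gi <- impute_missing(make_geno(calls), 1)
  expect_equal(unname(gi$calls[4, 1]), 0L)
  expect_false(anyNA(gi$calls))
})

test_that("mask-and-recover: imputed frequencies within 0.02 at n = 222", {
  g <- sim_unlinked_genotypes(222, 300, seed = 56)
  f_true <- popgenchip:::allele_frequencies(g)
  set.seed(57)
  masked <- g
  masked$calls[matrix(runif(length(g$calls)) < 0.10,
                      nrow(g$calls))] <- NA_integer_
  gi <- impute_missing(masked, seed = 58)
  f_imp <- popgenchip:::allele_frequencies(gi)
  expect_lt(max(abs(f_imp - f_true)), 0.05)   # worst single marker
  expect_lt(mean(abs(f_imp - f_true)), 0.02)  # typical marker
})

test_that("MAF spectrum bins are half-open and complete", {
  calls <- sapply(c(0.06, 0.15, 0.25, 0.45, 0.10), function(m) {
    k <- round(2 * 50 * m)
    c(rep(1L, k), rep(0L, 50 - k))
  })
  sp <- maf_spectrum(make_geno(calls))
  expect_equal(sp$bins$count, c(1L, 2L, 1L, 0L, 1L))  # 0.10 -> second bin
  expect_equal(sum(sp$bins$proportion), 1)
  expect_equal(sp$mean_maf, mean(c(0.06, 0.15, 0.25, 0.45, 0.10)))
})

test_that("planted QC violations are recovered and attributed exactly", {
  cfg <- sim_config(ne_epochs = list(c(20, 150)), n_chrom = 3,
                    n_markers_per_chrom = 120, n_samples = 120, seed = 66)
  h <- simulate_haplotypes(cfg)
  plant <- list(n_lowcall = 12, n_highmiss = 13, n_monomorphic = 10,
                n_hwe = 10, n_lowmaf = 15)
  sg <- sample_genotypes(h, missing_rate = 0.01, plant = plant, seed = 66)
  g <- sg$geno

  fs <- filter_samples(g, qc_config())
  removed_samples <- strsplit(fs$report$removed_ids, ",")[[1]]
  expect_setequal(removed_samples, sg$truth$highmiss)

  fv <- filter_variants(fs$geno, qc_config())
  rule <- setNames(fv$rule, fs$geno$variants$id)
  expect_true(all(rule[sg$truth$lowcall] == "call_rate"))
  expect_true(all(rule[sg$truth$monomorphic] == "monomorphic"))
  expect_true(all(rule[sg$truth$hwe] == "hwe"))
  expect_true(all(rule[sg$truth$lowmaf] %in% c("low_maf", "monomorphic")))
  # every plant is removed
  planted <- unlist(sg$truth[c("lowcall", "monomorphic", "hwe", "lowmaf")])
  expect_true(all(!planted %in% fv$geno$variants$id))
})
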