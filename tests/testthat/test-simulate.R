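test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(ne_epochs = list(c(10, 60)), n_chrom = 2,
                    n_markers_per_chrom = 50, n_samples = 30, seed = 5)
  h1 <- simulate_haplotypes(cfg)
  h2 <- simulate_haplotypes(cfg)
  expect_identical(h1$chroms[[1]]$haps, h2$chroms[[1]]$haps)
  expect_identical(h1$chroms[[2]]$pos, h2$chroms[[2]]$pos)
  g1 <- sample_genotypes(h1, seed = 9)
  g2 <- sample_genotypes(h2, seed = 9)
  expect_identical(g1$geno$calls, g2$geno$calls)
  cfg2 <- cfg; cfg2$seed <- 6L
  h3 <- simulate_haplotypes(cfg2)
  expect_false(identical(h1$chroms[[1]]$haps, h3$chroms[[1]]$haps))
})

test_that("without recombination offspring haplotypes are parental copies", {
  set.seed(7)
  haps <- matrix(sample(0:1, 20 * 30, replace = TRUE), 20, 30)
  storage.mode(haps) <- "integer"
  pos_m <- rep(0, 30)  # zero map length: no crossovers possible
  off <- popgenchip:::cpp_wf_generation(haps, pos_m, 10L)
  for (o in 1:10) {
    match_any <- any(apply(haps, 1, function(p) all(p == off[o, ])))
    expect_true(match_any)
  }
})

test_that("allele counts are conserved between haplotypes and genotypes", {
  cfg <- sim_config(ne_epochs = list(c(5, 40)), n_chrom = 1,
                    n_markers_per_chrom = 80, n_samples = 40, seed = 8)
  h <- simulate_haplotypes(cfg)
  sg <- sample_genotypes(h, seed = 8)
  H <- h$chroms[[1]]$haps
  # all diploids sampled: genotype column sums equal haplotype column sums
  expect_equal(unname(colSums(sg$geno$calls)[order(order(h$chroms[[1]]$pos))]),
               unname(colSums(H)))
})

test_that("heterozygosity decays at the Wright-Fisher drift rate", {
  ne <- 100; gens <- 20
  ratios <- sapply(1:8, function(r) {
    cfg <- sim_config(ne_epochs = list(c(gens, ne)), n_chrom = 1,
                      n_markers_per_chrom = 400, n_samples = ne,
                      recomb_rate = 1, seed = 200 + r)
    h <- simulate_haplotypes(cfg)
    H <- h$chroms[[1]]$haps
    f_end <- colMeans(H)
    mean(2 * f_end * (1 - f_end))
  })
  # expected decay from the founder spectrum mean heterozygosity
  set.seed(999)
  f <- pmin(pmax(rbeta(4000, 0.5, 0.5), 0.01), 0.99)
  h0 <- mean(2 * f * (1 - f))
  expected <- h0 * (1 - 1 / (2 * ne))^(gens + 1)  # +1 census generation
  expect_lt(abs(mean(ratios) - expected) / expected, 0.10)
})

test_that("masking hits the requested missingness rate", {
  cfg <- sim_config(ne_epochs = list(c(5, 150)), n_chrom = 2,
                    n_markers_per_chrom = 300, n_samples = 150, seed = 13)
  h <- simulate_haplotypes(cfg)
  sg <- sample_genotypes(h, missing_rate = 0.05, seed = 13)
  rate <- mean(is.na(sg$geno$calls))
  expect_lt(abs(rate - 0.05), 0.005)
  expect_false(anyNA(sg$geno_complete$calls))
})

test_that("phenotype variance bookkeeping matches the target h2", {
  g <- sim_unlinked_genotypes(500, 1500, seed = 14)
  tr0 <- data.frame(name = "T0", h2 = 0, n_causal = 100, mean = 50, sd = 5,
                    sex_effect = 0, farm_effect = 0, year_effect = 0)
  ph0 <- simulate_phenotypes(g, tr0, seed = 15)
  expect_lt(abs(cor(ph0$pheno$T0, ph0$truth$T0$bv + rnorm(500))), 0.15)
  tr1 <- data.frame(name = "T1", h2 = 1, n_causal = 100, mean = 50, sd = 5,
                    sex_effect = 0, farm_effect = 0, year_effect = 0)
  ph1 <- simulate_phenotypes(g, tr1, seed = 16)
  expect_equal(ph1$pheno$T1, 50 + ph1$truth$T1$bv)
  tr4 <- data.frame(name = "T4", h2 = 0.4, n_causal = 200, mean = 100,
                    sd = 10, sex_effect = 0, farm_effect = 0,
                    year_effect = 0)
  ph4 <- simulate_phenotypes(g, tr4, seed = 17)
  ratio <- var(ph4$truth$T4$bv) /
    (var(ph4$truth$T4$bv) + var(ph4$pheno$T4 - ph4$truth$T4$bv - 100))
  expect_lt(abs(ratio - 0.4), 0.04)
})

test_that("emitted datasets round-trip through the PLINK text reader", {
  cfg <- sim_config(ne_epochs = list(c(5, 50)), n_chrom = 2,
                    n_markers_per_chrom = 40, n_samples = 25,
                    missing_rate = 0.01, seed = 18,
                    traits = data.frame(name = "WH", h2 = 0.3,
                                        n_causal = 20, mean = 115, sd = 7,
                                        sex_effect = 3, farm_effect = 2,
                                        year_effect = 0.5))
  out <- emit_dataset(cfg, file.path(tempdir(), "emit1"))
  g <- read_plink_text(out[["ped"]], out[["map"]])
  expect_equal(dim(g$calls), c(25L, 80L))
  ph <- read_phenotypes(out[["pheno"]])
  expect_equal(nrow(ph), 25)
  expect_true(all(ph$WH > 0))
  tb <- read.table(out[["truth"]], header = TRUE)
  expect_equal(nrow(tb), 25)
})

test_that("the herd preset yields a mean MAF near 0.2 after QC", {
  cfg <- dabieshan_preset(seed = 3, n_markers_per_chrom = 200)
  h <- simulate_haplotypes(cfg)
  sg <- sample_genotypes(h, missing_rate = 0, seed = 3)
  qc <- run_qc(sg$geno, seed = 3)
  sp <- maf_spectrum(qc$geno)
  expect_lt(abs(sp$mean_maf - 0.2), 0.05)
  # every category is populated; the real chip's strong low-MAF skew is
  # an ascertainment feature the neutral generator does not emulate
  expect_true(all(sp$bins$count > 0))
  expect_gt(sp$n_below_0.05, 0)
})

test_that("oversampling beyond the available diploids errors", {
  cfg <- sim_config(ne_epochs = list(c(3, 20)), n_chrom = 1,
                    n_markers_per_chrom = 30, n_samples = 10, seed = 19)
  h <- simulate_haplotypes(cfg)
  expect_error(sample_genotypes(h, n_samples = 11, seed = 19),
               "only 10 diploids")
})
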