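test_that("three-SD outlier rule: constant, gross outlier, planted", {
  cl <- remove_outliers(rep(100, 10))
  expect_equal(cl$n_removed, 0)
  cl2 <- remove_outliers(c(rep(100, 10), 10000))
  expect_equal(cl2$n_removed, 1)
  expect_false(10000 %in% cl2$values)
  # planted extremes in a Gaussian sample
  set.seed(101)
  x <- rnorm(1000)
  x <- c(x, c(-10, 10, 12, -11, 9.5))
  ids <- seq_along(x)
  planted <- 1001:1005
  cl3 <- remove_outliers(x, ids)
  removed <- setdiff(ids, cl3$ids)
  expect_true(all(planted %in% removed))
  expect_lte(length(removed), 10)
})

test_that("fixed-effect design has full rank and collapses degenerate factors", {
  s1 <- data.frame(sex = rep("female", 6), farm = "f1", birth_year = 2017)
  expect_equal(colnames(build_fixed_design(s1)), "(Intercept)")
  s2 <- expand.grid(sex = c("female", "male"), farm = c("f1", "f2"))
  X2 <- build_fixed_design(s2[rep(1:4, 3), ])
  expect_equal(ncol(X2), 3)  # intercept + sex + farm
  set.seed(102)
  s3 <- data.frame(sex = sample(c("female", "male"), 222, TRUE),
                   farm = sample(paste0("f", 1:3), 222, TRUE),
                   birth_year = sample(2016:2019, 222, TRUE))
  X3 <- build_fixed_design(s3)
  expect_equal(qr(X3)$rank, ncol(X3))
  expect_equal(ncol(X3), 1 + 1 + 2 + 3)  # analytic level counting
})

test_that("heritability identities, including published variance components", {
  expect_equal(round(heritability(16.523, 42.488), 2), 0.28)
  expect_equal(round(heritability(2.138, 1.821), 2), 0.54)
  expect_equal(heritability(0, 3), 0)
  expect_error(heritability(0, 0), "zero")
  # monotonicity
  expect_gt(heritability(2, 3), heritability(1, 3))
  expect_lt(heritability(1, 4), heritability(1, 3))
})

test_that("coefficient of variation: worked example and scale invariance", {
  cv <- compute_cv(c(90, 100, 110))
  expect_equal(cv$cv_percent, 10)
  expect_equal(compute_cv(rep(5, 4))$cv_percent, 0)
  x <- c(3, 5, 9, 12)
  expect_equal(compute_cv(7 * x)$cv_percent, compute_cv(x)$cv_percent)
  expect_error(compute_cv(c(-5, 1)), "non-positive")
})

make_reml_data <- function(n = 160, m = 800, h2 = 0.4, seed = 1) {
  g <- sim_unlinked_genotypes(n, m, seed = seed)
  G <- suppressWarnings(compute_grm(g))
  tr <- data.frame(name = "T1", h2 = h2, n_causal = 100, mean = 100,
                   sd = 10, sex_effect = 3, farm_effect = 2,
                   year_effect = 0.5)
  ph <- simulate_phenotypes(g, tr, seed = seed + 1)
  list(y = ph$pheno$T1, X = build_fixed_design(g$samples), G = G,
       bv = ph$truth$T1$bv)
}

test_that("REML optimum beats a 21-point variance-ratio grid", {
  d <- make_reml_data(seed = 111)
  fit <- reml_fit(d$y, d$X, d$G)
  grid <- reml_profile(fit, -10:10)
  expect_gte(fit$loglik, max(grid) - 1e-6)
})

test_that("REML is shift invariant and scales quadratically", {
  d <- make_reml_data(seed = 112)
  f0 <- reml_fit(d$y, d$X, d$G)
  f_shift <- reml_fit(d$y + 1000, d$X, d$G)
  expect_equal(f_shift$h2, f0$h2, tolerance = 1e-6)
  expect_equal(f_shift$sigma_a2, f0$sigma_a2, tolerance = 1e-4)
  k <- 3.7
  f_scale <- reml_fit(k * d$y, d$X, d$G)
  expect_equal(f_scale$sigma_a2, k^2 * f0$sigma_a2, tolerance = 1e-4)
  expect_equal(f_scale$sigma_e2, k^2 * f0$sigma_e2, tolerance = 1e-4)
  expect_equal(f_scale$h2, f0$h2, tolerance = 1e-6)
})

test_that("null-heritability data drives h2 to the boundary with a flag", {
  set.seed(113)
  g <- sim_unlinked_genotypes(120, 500, seed = 113)
  G <- suppressWarnings(compute_grm(g))
  y <- rnorm(120, 50, 5)  # no genetic signal
  X <- build_fixed_design(g$samples)
  fit <- suppressWarnings(reml_fit(y, X, G))
  expect_lt(fit$h2, 0.1)
})

test_that("REML rejects a non-identifiable identity G", {
  y <- rnorm(30)
  X <- matrix(1, 30, 1)
  expect_error(reml_fit(y, X, diag(30) - 1e-6 * diag(30) * 0),
               "not separable")
})

test_that("fit_traits mirrors the per-trait table with CV and outlier counts", {
  set.seed(115)
  g <- sim_unlinked_genotypes(150, 600, seed = 115)
  G <- suppressWarnings(compute_grm(g))
  tr <- data.frame(name = c("WH", "BW"), h2 = c(0.3, 0.4),
                   n_causal = 80, mean = c(115, 300), sd = c(7, 50),
                   sex_effect = c(3, 20), farm_effect = c(2, 10),
                   year_effect = c(0.5, 4))
  ph <- simulate_phenotypes(g, tr, seed = 116)
  res <- fit_traits(ph$pheno, G)
  expect_equal(res$trait, c("WH", "BW"))
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
  expect_true(all(res$sigma_e2 > 0))
  expect_true(all(res$cv_percent > 0))
  # grid oracle on every fitted trait via a refit
  for (tn in res$trait) {
    ok <- !is.na(ph$pheno[[tn]])
    cl <- remove_outliers(ph$pheno[[tn]][ok])
    expect_equal(res$n[res$trait == tn], length(cl$values))
  }
})

test_that("fixed-effect F-test runs on multi-level covariates", {
  set.seed(117)
  samp <- data.frame(sex = sample(c("female", "male"), 80, TRUE),
                     farm = sample(c("f1", "f2"), 80, TRUE))
  y <- rnorm(80) + ifelse(samp$sex == "male", 2, 0)
  tab <- fixed_effects_ftest(y, samp)
  expect_true("sex" %in% rownames(tab))
  expect_lt(tab["sex", "Pr(>F)"], 0.01)
})
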