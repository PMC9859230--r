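#' Simulation configuration
#'
#' Parameters of the Wright-Fisher forward simulator. The population is a
#' set of diploids of piecewise-constant effective size; marker alleles
#' start from a Beta(0.5, 0.5)-shaped standing frequency spectrum
#' (truncated to \[0.01, 0.99\]) in linkage equilibrium, and each
#' generation recombines gametes under Haldane's no-interference model.
#' There is no mutation, selection or migration: the object of study is
#' standing chip variation.
#'
#' @param ne_epochs list of `c(duration_generations, Ne)` pairs, oldest
#'   first; the simulation runs through them in order and ends at the
#'   most recent epoch.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_markers_per_chrom markers per chromosome (random positions).
#' @param recomb_rate recombination rate in cM/Mb.
#' @param n_samples diploid individuals genotyped from the final
#'   generation.
#' @param maf_shape both shape parameters of the symmetric Beta founder
#'   frequency spectrum.
#' @param traits data frame of trait specs (columns `name`, `h2`,
#'   `n_causal`, `mean`, `sd`, `sex_effect`, `farm_effect`,
#'   `year_effect`), or NULL for no phenotypes.
#' @param missing_rate background genotype missingness introduced when
#'   sampling.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ne_epochs = list(c(50, 200)), n_chrom = 2,
                       chrom_length = 10e6, n_markers_per_chrom = 200,
                       recomb_rate = 1.0, n_samples = 100,
                       maf_shape = 0.5, traits = NULL,
                       missing_rate = 0, seed = 1L) {
  stopifnot(length(ne_epochs) >= 1, n_chrom >= 1, chrom_length > 0,
            n_markers_per_chrom >= 2, recomb_rate > 0, n_samples >= 1,
            missing_rate >= 0, missing_rate < 1)
  for (ep in ne_epochs) stopifnot(length(ep) == 2, all(ep >= 1))
  structure(list(ne_epochs = ne_epochs, n_chrom = n_chrom,
                 chrom_length = chrom_length,
                 n_markers_per_chrom = n_markers_per_chrom,
                 recomb_rate = recomb_rate, n_samples = n_samples,
                 maf_shape = maf_shape, traits = traits,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Scaled-down preset emulating a small indigenous cattle herd
#'
#' Two-epoch history (ancestral Ne 1000 for 160 generations, then a
#' recent epoch at Ne 86), five 10-Mb chromosomes at ~30 kb marker
#' spacing, 235 genotyped individuals with an 85/15 female/male split
#' across three farms and four birth years, 2% background missingness,
#' and nine body-measurement/weight traits whose heritabilities span
#' 0.12-0.54 and coefficients of variation span ~6-20%.
#'
#' @param seed RNG seed.
#' @param n_markers_per_chrom markers per chromosome (default 334).
#' @return A `sim_config`.
#' @export
dabieshan_preset <- function(seed = 1L, n_markers_per_chrom = 334) {
  traits <- data.frame(
    name = c("WH", "HHC", "DBL", "CG", "AC", "WAW", "IEW", "SC", "BW"),
    h2 = c(0.28, 0.41, 0.28, 0.30, 0.14, 0.19, 0.12, 0.54, 0.37),
    n_causal = 100,
    mean = c(115, 118, 130, 165, 190, 40, 17, 16, 300),
    sd = c(7.3, 7.1, 11.0, 21.0, 25.0, 5.0, 3.4, 2.0, 56.0),
    sex_effect = c(4, 4, 5, 8, 8, 1.5, 1, 0.8, 30),
    farm_effect = c(2, 2, 3, 5, 6, 1, 0.8, 0.5, 15),
    year_effect = c(0.5, 0.5, 0.8, 1.5, 1.5, 0.3, 0.2, 0.1, 5),
    stringsAsFactors = FALSE)
  sim_config(ne_epochs = list(c(160, 1000), c(20, 86)), n_chrom = 5,
             chrom_length = 10e6,
             n_markers_per_chrom = n_markers_per_chrom,
             recomb_rate = 1.0, n_samples = 235, maf_shape = 0.5,
             traits = traits, missing_rate = 0.02, seed = seed)
}

#' Forward-simulate phased haplotypes
#'
#' Discrete-generation Wright-Fisher simulation with recombination under
#' the configured piecewise-constant Ne history. The founder generation
#' draws marker frequencies from the truncated Beta spectrum and
#' haplotypes in linkage equilibrium; each later generation is formed by
#' gametes of random parents with Poisson crossover counts. After the
#' last epoch one further generation of `2 n_samples` gametes is bred
#' from the final effective pool — the "census" generation that gets
#' genotyped, which may be larger than the effective size itself.
#'
#' @param cfg a [sim_config()].
#' @return A `hap_set` list: per-chromosome `haps` (2 n_samples x L 0/1
#'   matrices) and `pos`, plus `ne_history` (realized size per
#'   generation, oldest first) and the config.
#' @export
simulate_haplotypes <- function(cfg) {
  set.seed(cfg$seed)
  ne0 <- cfg$ne_epochs[[1]][2]
  chroms <- vector("list", cfg$n_chrom)
  for (ch in seq_len(cfg$n_chrom)) {
    L <- cfg$n_markers_per_chrom
    pos <- sort(sample.int(cfg$chrom_length, L))
    f <- rbeta(L, cfg$maf_shape, cfg$maf_shape)
    f <- pmin(pmax(f, 0.01), 0.99)
    haps <- matrix(rbinom(2 * ne0 * L, 1L, rep(f, each = 2 * ne0)),
                   nrow = 2 * ne0, ncol = L)
    storage.mode(haps) <- "integer"
    chroms[[ch]] <- list(haps = haps, pos = pos,
                         pos_m = pos * cfg$recomb_rate * 1e-8)
  }
  ne_history <- integer(0)
  for (ep in cfg$ne_epochs) {
    dur <- ep[1]; ne <- ep[2]
    for (gen in seq_len(dur)) {
      for (ch in seq_len(cfg$n_chrom)) {
        chroms[[ch]]$haps <- cpp_wf_generation(chroms[[ch]]$haps,
                                               chroms[[ch]]$pos_m, 2L * ne)
      }
      ne_history <- c(ne_history, ne)
    }
  }
  # census generation actually genotyped
  for (ch in seq_len(cfg$n_chrom)) {
    chroms[[ch]]$haps <- cpp_wf_generation(chroms[[ch]]$haps,
                                           chroms[[ch]]$pos_m,
                                           2L * cfg$n_samples)
  }
  structure(list(chroms = chroms, ne_history = ne_history, config = cfg),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("hap_set: %d chromosome(s) x %d markers, %d haplotypes\n",
              length(x$chroms), ncol(x$chroms[[1]]$haps),
              nrow(x$chroms[[1]]$haps)))
  invisible(x)
}

default_covariates <- function(n) {
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(199, 36) / 235)
  farm <- sample(paste0("farm", 1:3), n, replace = TRUE)
  birth_year <- sample(2016:2019, n, replace = TRUE)
  data.frame(id = sprintf("S%04d", seq_len(n)), sex = sex, farm = farm,
             birth_year = birth_year, stringsAsFactors = FALSE)
}

#' Collapse haplotypes to diploid genotypes, with optional planted faults
#'
#' Consecutive haplotype pairs form diploids; calls count copies of the
#' "1" allele (labelled B). Background missingness and deliberate QC
#' violations — low-call-rate variants, high-missingness samples,
#' monomorphic, all-heterozygote (Hardy-Weinberg-violating) and very rare
#' variants — can be planted, and every plant is recorded in the returned
#' truth table so filters can be audited against ground truth.
#'
#' @param haps a `hap_set` from [simulate_haplotypes()].
#' @param n_samples diploids to genotype (default: all available).
#' @param missing_rate background per-call masking probability.
#' @param plant optional list with any of `n_lowcall`, `n_highmiss`,
#'   `n_monomorphic`, `n_hwe`, `n_lowmaf` (counts of planted faults).
#' @param seed RNG seed for masking/planting and covariate assignment.
#' @return List: `geno` (a [geno_matrix]), `geno_complete` (the same
#'   matrix before any masking — the true genotypes), `truth` (planted
#'   variant/sample ids by rule).
#' @export
sample_genotypes <- function(haps, n_samples = NULL, missing_rate = 0,
                             plant = NULL, seed = 1L) {
  set.seed(seed)
  nh <- nrow(haps$chroms[[1]]$haps)
  if (nh %% 2 != 0) stop("odd haplotype count cannot form diploids")
  avail <- nh %/% 2
  if (is.null(n_samples)) n_samples <- avail
  if (n_samples > avail)
    stop(sprintf("requested %d samples but only %d diploids available",
                 n_samples, avail))
  pick <- sort(sample.int(avail, n_samples))
  calls <- NULL
  variants <- NULL
  for (ch in seq_along(haps$chroms)) {
    h <- haps$chroms[[ch]]$haps
    g <- h[2 * pick - 1, , drop = FALSE] + h[2 * pick, , drop = FALSE]
    calls <- cbind(calls, g)
    L <- ncol(h)
    variants <- rbind(variants, data.frame(
      id = sprintf("chr%d_%d", ch, haps$chroms[[ch]]$pos),
      chrom = ch, pos = haps$chroms[[ch]]$pos,
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE))
  }
  storage.mode(calls) <- "integer"
  n <- nrow(calls); m <- ncol(calls)
  complete_calls <- calls
  truth <- list(lowcall = integer(0), highmiss = integer(0),
                monomorphic = integer(0), hwe = integer(0),
                lowmaf = integer(0))
  reserved <- integer(0)
  if (!is.null(plant)) {
    take <- function(k) {
      free <- setdiff(seq_len(m), reserved)
      v <- sort(sample(free, k))
      reserved <<- c(reserved, v)
      v
    }
    if (!is.null(plant$n_monomorphic) && plant$n_monomorphic > 0) {
      truth$monomorphic <- take(plant$n_monomorphic)
      calls[, truth$monomorphic] <- 0L
      complete_calls[, truth$monomorphic] <- 0L
    }
    if (!is.null(plant$n_hwe) && plant$n_hwe > 0) {
      truth$hwe <- take(plant$n_hwe)
      calls[, truth$hwe] <- 1L
      complete_calls[, truth$hwe] <- 1L
    }
    if (!is.null(plant$n_lowmaf) && plant$n_lowmaf > 0) {
      truth$lowmaf <- take(plant$n_lowmaf)
      for (j in truth$lowmaf) {
        calls[, j] <- 0L
        calls[sample.int(n, 1), j] <- 1L
        complete_calls[, j] <- calls[, j]
      }
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(runif(n * m) < missing_rate, n, m)
    mask[, reserved] <- FALSE
    calls[mask] <- NA_integer_
  }
  if (!is.null(plant)) {
    if (!is.null(plant$n_lowcall) && plant$n_lowcall > 0) {
      truth$lowcall <- take(plant$n_lowcall)
      for (j in truth$lowcall)
        calls[runif(n) < 0.20, j] <- NA_integer_
    }
    if (!is.null(plant$n_highmiss) && plant$n_highmiss > 0) {
      truth$highmiss <- sort(sample.int(n, plant$n_highmiss))
      for (s in truth$highmiss) {
        hide <- runif(m) < 0.10
        hide[reserved] <- FALSE
        calls[s, hide] <- NA_integer_
      }
    }
  }
  samples <- default_covariates(n)
  g <- geno_matrix(calls, variants, samples)
  # planted indices -> stable ids (geno_matrix reorders variants)
  highmiss_idx <- truth$highmiss
  truth <- lapply(truth, function(ix) variants$id[ix])
  truth$highmiss <- samples$id[highmiss_idx]
  complete <- if (anyNA(calls))
    geno_matrix(complete_calls, variants, samples) else g
  list(geno = g, geno_complete = complete, truth = truth)
}

#' Simulate phenotypes with known heritability over real genotypes
#'
#' For each trait spec: draw `n_causal` polymorphic causal markers with
#' normal effects, rescale breeding values to variance h2 * sd^2, add
#' independent residuals of variance (1 - h2) * sd^2, and add fixed
#' effects — a sex contrast, farm contrasts, and a linear birth-year
#' trend — of the configured sizes. True breeding values and causal
#' effects are returned for recovery tests.
#'
#' @param g a [geno_matrix] whose samples carry sex/farm/birth_year.
#' @param traits trait-spec data frame (see [sim_config()]).
#' @param seed RNG seed.
#' @return List: `pheno` (data frame, one row per sample), `truth`
#'   (per-trait list with `bv`, `causal`, `beta`).
#' @export
simulate_phenotypes <- function(g, traits, seed = 1L) {
  set.seed(seed)
  n <- n_samples(g)
  f <- allele_frequencies(g)
  poly <- which(f > 0 & f < 1)
  pheno <- data.frame(id = g$samples$id, sex = g$samples$sex,
                      farm = g$samples$farm,
                      birth_year = g$samples$birth_year,
                      stringsAsFactors = FALSE)
  truth <- list()
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    if (tr$n_causal > length(poly)) stop("more causal markers than polymorphic markers")
    causal <- sort(sample(poly, tr$n_causal))
    beta <- rnorm(tr$n_causal)
    Zc <- sweep(g$calls[, causal, drop = FALSE], 2, 2 * f[causal], `-`)
    bv <- unname(drop(Zc %*% beta))
    target_va <- tr$h2 * tr$sd^2
    if (var(bv) > 0) bv <- bv * sqrt(target_va / var(bv))
    e <- rnorm(n, 0, sqrt((1 - tr$h2) * tr$sd^2))
    fx <- rep(0, n)
    if (!is.null(tr$sex_effect) && !all(is.na(g$samples$sex)))
      fx <- fx + ifelse(g$samples$sex == "male", tr$sex_effect, 0)
    if (!is.null(tr$farm_effect) && !is.null(g$samples$farm)) {
      lev <- sort(unique(g$samples$farm))
      eff <- tr$farm_effect * (seq_along(lev) - mean(seq_along(lev)))
      fx <- fx + eff[match(g$samples$farm, lev)]
    }
    if (!is.null(tr$year_effect) && !is.null(g$samples$birth_year))
      fx <- fx + tr$year_effect *
        (g$samples$birth_year - mean(g$samples$birth_year))
    y <- tr$mean + bv + e + fx
    y <- pmax(y, 0.01 * tr$mean) # traits are physical measurements, > 0
    pheno[[tr$name]] <- y
    truth[[tr$name]] <- list(bv = bv, causal = g$variants$id[causal],
                             beta = beta)
  }
  list(pheno = pheno, truth = truth)
}

#' Simulate and write a complete dataset to disk
#'
#' Runs the simulator under the given config and writes PLINK text
#' genotypes, a phenotype/covariate table and a tab-separated truth file
#' of true breeding values.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
emit_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  haps <- simulate_haplotypes(cfg)
  sg <- sample_genotypes(haps, n_samples = cfg$n_samples,
                         missing_rate = cfg$missing_rate,
                         seed = cfg$seed + 1L)
  paths <- write_plink_text(sg$geno, file.path(out_dir, "genotypes"))
  out <- c(paths)
  if (!is.null(cfg$traits)) {
    ph <- simulate_phenotypes(sg$geno_complete, cfg$traits,
                              seed = cfg$seed + 2L)
    ppath <- file.path(out_dir, "phenotypes.tsv")
    write.table(ph$pheno, ppath, quote = FALSE, sep = "\t",
                row.names = FALSE)
    bv <- data.frame(id = sg$geno$samples$id)
    for (nm in names(ph$truth)) bv[[paste0("bv_", nm)]] <- ph$truth[[nm]]$bv
    tpath <- file.path(out_dir, "truth_bv.tsv")
    write.table(bv, tpath, quote = FALSE, sep = "\t", row.names = FALSE)
    out <- c(out, pheno = ppath, truth = tpath)
  }
  out
}

#' Independent-marker genotypes with a given frequency spectrum
#'
#' Draws unlinked genotypes directly as Binomial(2, f) with f from the
#' truncated Beta spectrum — the quick generator used for variance
#' -component experiments, where marker-to-marker linkage is irrelevant.
#'
#' @param n samples.
#' @param m markers.
#' @param maf_shape Beta shape (symmetric).
#' @param seed RNG seed.
#' @return A [geno_matrix] on a single synthetic chromosome.
#' @export
sim_unlinked_genotypes <- function(n, m, maf_shape = 0.5, seed = 1L) {
  set.seed(seed)
  f <- pmin(pmax(rbeta(m, maf_shape, maf_shape), 0.05), 0.95)
  calls <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
  storage.mode(calls) <- "integer"
  pos <- sort(sample.int(2^30, m))
  variants <- data.frame(id = paste0("m", seq_len(m)), chrom = 1L,
                         pos = pos, allele_a = "A", allele_b = "B",
                         stringsAsFactors = FALSE)
  geno_matrix(calls, variants, default_covariates(n))
}
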