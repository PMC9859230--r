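#' Pipeline configuration
#'
#' Bundles the stage configurations and I/O paths of a full run. With
#' `ped`/`map` set the pipeline analyses existing PLINK text data;
#' otherwise it simulates a dataset from `sim` first.
#'
#' @param out_dir output directory.
#' @param ped,map optional input PLINK text paths.
#' @param pheno optional phenotype table path.
#' @param sim a [sim_config()] used when no input files are given.
#' @param qc a [qc_config()].
#' @param ne an [ne_config()].
#' @param ld_max_bp,ld_bin_width,ld_max_dist LD window and binning.
#' @param n_pcs leading principal components to report.
#' @param seed run seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, ped = NULL, map = NULL, pheno = NULL,
                       sim = dabieshan_preset(), qc = qc_config(),
                       ne = ne_config(), ld_max_bp = 1e6,
                       ld_bin_width = 2500, ld_max_dist = 5e5,
                       n_pcs = 2, seed = 1L) {
  structure(list(out_dir = out_dir, ped = ped, map = map, pheno = pheno,
                 sim = sim, qc = qc, ne = ne, ld_max_bp = ld_max_bp,
                 ld_bin_width = ld_bin_width, ld_max_dist = ld_max_dist,
                 n_pcs = n_pcs, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

write_tsv <- function(x, path) {
  write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (simulate) -> qc -> maf -> ld -> ne -> grm -> pca ->
#' reml. Each stage writes its table under `out_dir` and registers row
#' counts in the manifest. A missing phenotype table skips the REML stage
#' with a warning; any other stage failure halts the run with the failing
#' stage named.
#'
#' @param cfg a [run_config()].
#' @return A `run_manifest` list: `stages` (data frame of per-stage row
#'   counts and outputs), `seed`, and the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(stage, n_in, n_out, path) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, output = path)
  }
  results <- list()
  stage <- "input"
  tryCatch({
    if (is.null(cfg$ped)) {
      stage <- "simulate"
      sim <- cfg$sim
      sim$seed <- cfg$seed
      paths <- emit_dataset(sim, file.path(cfg$out_dir, "simulated"))
      cfg$ped <- paths[["ped"]]
      cfg$map <- paths[["map"]]
      if ("pheno" %in% names(paths)) cfg$pheno <- paths[["pheno"]]
      pipeline_log(stage, "wrote %s", paste(basename(paths), collapse = ", "))
    }
    stage <- "read"
    g <- read_plink_text(cfg$ped, cfg$map)
    pipeline_log(stage, "%d samples x %d variants", nrow(g$calls),
                 ncol(g$calls))
    note("read", NA, ncol(g$calls), cfg$ped)

    stage <- "qc"
    pipeline_log(stage, paste("thresholds: call rate >= %.2f, MAF >= %.3f,",
                              "HWE p >= %g, sample missingness <= %.2f,",
                              "dedup r2 > %.3f"),
                 cfg$qc$min_call_rate, cfg$qc$min_maf, cfg$qc$hwe_alpha,
                 cfg$qc$max_sample_missingness, cfg$qc$dedup_r2)
    qcres <- run_qc(g, cfg$qc, seed = cfg$seed)
    p <- write_tsv(qcres$report, file.path(cfg$out_dir, "qc_report.tsv"))
    write_tsv(qcres$chrom_summary,
              file.path(cfg$out_dir, "qc_chromosomes.tsv"))
    note("qc", ncol(g$calls), ncol(qcres$geno$calls), p)
    gq <- qcres$geno
    results$qc <- qcres
    pipeline_log(stage, "retained %d samples x %d variants",
                 nrow(gq$calls), ncol(gq$calls))

    stage <- "maf"
    sp <- maf_spectrum(gq)
    p <- write_tsv(sp$bins, file.path(cfg$out_dir, "maf_spectrum.tsv"))
    note("maf", ncol(gq$calls), nrow(sp$bins), p)
    results$maf <- sp
    pipeline_log(stage, "mean MAF %.3f", sp$mean_maf)

    stage <- "ld"
    pairs <- pairwise_ld_window(gq, max_bp = cfg$ld_max_bp)
    bins <- decay_bins(pairs, bin_width = cfg$ld_bin_width,
                       max_dist = cfg$ld_max_dist)
    p <- write_tsv(bins, file.path(cfg$out_dir, "ld_decay.tsv"))
    note("ld", ncol(gq$calls), nrow(bins), p)
    results$ld <- list(pairs = pairs, bins = bins)
    pipeline_log(stage, "%d pairs; mean r2 %.3f at 0-50 kb", nrow(pairs),
                 mean_r2_range(pairs, 0, 5e4))

    stage <- "ne"
    traj <- ne_trajectory(bins, nrow(gq$calls), cfg$ne)
    p <- write_tsv(traj, file.path(cfg$out_dir, "ne_trajectory.tsv"))
    note("ne", nrow(bins), nrow(traj), p)
    results$ne <- traj
    pipeline_log(stage, "Ne %.0f at t=%.1f ... %.0f at t=%.1f",
                 traj$ne[1], traj$t[1], traj$ne[nrow(traj)],
                 traj$t[nrow(traj)])

    stage <- "grm"
    G <- compute_grm(gq)
    paths <- write_grm_text(G, file.path(cfg$out_dir, "grm"))
    note("grm", ncol(gq$calls), nrow(G$values), paths[["grm"]])
    results$grm <- G
    pipeline_log(stage, "mean kinship (off-diagonal of G) %.4f",
                 mean_kinship(G))

    stage <- "pca"
    pca <- grm_pca(G, k = cfg$n_pcs)
    sc <- data.frame(id = pca$ids, pca$scores)
    p <- write_tsv(sc, file.path(cfg$out_dir, "pca_scores.tsv"))
    note("pca", nrow(G$values), nrow(sc), p)
    results$pca <- pca
    pipeline_log(stage, "PC1+PC2 explain %.2f%% of variance",
                 100 * sum(pca$var_frac[seq_len(min(2, cfg$n_pcs))]))

    stage <- "reml"
    if (is.null(cfg$pheno) || !file.exists(cfg$pheno)) {
      warning("no phenotype table: REML stage skipped")
    } else {
      ph <- read_phenotypes(cfg$pheno)
      ph <- match_phenotypes(gq, ph)
      fits <- fit_traits(ph, G)
      p <- write_tsv(fits, file.path(cfg$out_dir, "heritability.tsv"))
      note("reml", nrow(ph), nrow(fits), p)
      results$reml <- fits
      pipeline_log(stage, "fitted %d trait(s); h2 range %.2f-%.2f",
                   nrow(fits), min(fits$h2), max(fits$h2))
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- do.call(rbind, stages)
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  structure(list(stages = manifest, seed = cfg$seed, results = results),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d stage(s) completed\n", x$seed,
              nrow(x$stages)))
  print(x$stages, row.names = FALSE)
  invisible(x)
}
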