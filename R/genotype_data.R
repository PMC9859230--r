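#' @useDynLib popgenchip, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor optimize p.adjust pchisq rbinom rnorm rpois runif sd
#'   var median aggregate anova as.formula lm model.matrix quantile rbeta
#' @importFrom utils read.table write.table
NULL

AUTOSOMES <- 1:29

#' Construct a genotype matrix object
#'
#' The central container of the package: diploid genotype calls for a set
#' of samples at a set of autosomal biallelic markers. Calls count copies
#' of `allele_b` (0, 1, 2); missing calls are `NA`.
#'
#' @param calls integer matrix, samples x variants, values in `c(0,1,2,NA)`.
#' @param variants data frame with columns `id`, `chrom` (1-29), `pos`
#'   (1-based bp), `allele_a`, `allele_b`.
#' @param samples data frame with at least a column `id`; optional `sex`,
#'   `farm`, `birth_year` covariate columns.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(variants))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(!variants$chrom %in% AUTOSOMES))
    stop("variants must lie on autosomes 1-29")
  if (any(variants$pos < 1L)) stop("positions are 1-based; pos >= 1 required")
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$id, variants$id)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%d chromosomes)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

n_samples <- function(g) nrow(g$calls)
n_variants <- function(g) ncol(g$calls)

subset_geno <- function(g, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  if (is.null(variants)) variants <- seq_len(n_variants(g))
  geno_matrix(g$calls[samples, variants, drop = FALSE],
              g$variants[variants, , drop = FALSE],
              g$samples[samples, , drop = FALSE])
}

#' B-allele frequency at one variant
#'
#' Frequency of `allele_b` among non-missing calls:
#' (het + 2 hom_b) / (2 n_nonmissing). The minor allele frequency is
#' `min(f, 1 - f)`.
#'
#' @param g a [geno_matrix].
#' @param variant_index column index of the variant.
#' @return Frequency in \[0, 1\].
#' @export
allele_frequency <- function(g, variant_index) {
  x <- g$calls[, variant_index]
  x <- x[!is.na(x)]
  if (!length(x)) stop("allele frequency undefined: all calls missing")
  sum(x) / (2 * length(x))
}

# Vectorised B-allele frequencies over all variants (NA-aware).
allele_frequencies <- function(g) {
  nm <- colSums(!is.na(g$calls))
  if (any(nm == 0)) stop("allele frequency undefined: all-missing variant")
  colSums(g$calls, na.rm = TRUE) / (2 * nm)
}

variant_maf <- function(g) {
  f <- allele_frequencies(g)
  pmin(f, 1 - f)
}

variant_call_rate <- function(g) colMeans(!is.na(g$calls))

sample_missingness <- function(g) rowMeans(is.na(g$calls))

#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses a whitespace-delimited PED file and its companion MAP file into a
#' [geno_matrix]. The B allele at each marker is the minor allele observed
#' in the file (ties at f = 0.5 broken lexicographically); "0" alleles are
#' treated as missing. Variants on chromosome codes outside 1-29 are
#' dropped with a warning.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (chrom, id, cM, pos).
#' @return A [geno_matrix].
#' @export
read_plink_text <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos"))
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file is empty")
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  need <- 6 + 2 * m
  nl <- lengths(toks)
  if (any(nl != need))
    stop(sprintf("PED parse error at line %d: expected %d fields, found %d",
                 which(nl != need)[1], need, nl[which(nl != need)[1]]))
  n <- length(toks)
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  ids <- character(n)
  sexes <- integer(n)
  for (s in seq_len(n)) {
    tk <- toks[[s]]
    ids[s] <- tk[2]
    sexes[s] <- suppressWarnings(as.integer(tk[5]))
    gt <- tk[-(1:6)]
    a1[s, ] <- gt[seq(1, 2 * m, by = 2)]
    a2[s, ] <- gt[seq(2, 2 * m, by = 2)]
  }
  keep <- map$chrom %in% AUTOSOMES
  if (any(!keep)) {
    warning(sprintf("dropped %d variant(s) on non-autosomal chromosome codes",
                    sum(!keep)))
    map <- map[keep, , drop = FALSE]
    a1 <- a1[, keep, drop = FALSE]
    a2 <- a2[, keep, drop = FALSE]
    m <- nrow(map)
  }
  calls <- matrix(NA_integer_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    al <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(al) == 0) al <- c("A", "B")
    if (length(al) == 1) al <- c(al, al)
    if (length(al) > 2)
      stop(sprintf("marker %s has more than two alleles", map$id[j]))
    cnt2 <- sum(x1[!miss] == al[2]) + sum(x2[!miss] == al[2])
    tot <- 2 * sum(!miss)
    f2 <- if (tot > 0) cnt2 / tot else 0
    # B = minor allele; tie (f = 0.5) broken lexicographically
    if (f2 > 0.5 || (f2 == 0.5 && al[2] > al[1])) {
      minor <- al[1]; major <- al[2]
    } else {
      minor <- al[2]; major <- al[1]
    }
    if (al[1] == al[2]) { minor <- al[1]; major <- al[1] }
    allele_a[j] <- major
    allele_b[j] <- minor
    cj <- (x1 == minor) + (x2 == minor)
    cj[miss] <- NA_integer_
    calls[, j] <- as.integer(cj)
  }
  sex <- ifelse(sexes == 2, "female", ifelse(sexes == 1, "male", NA))
  variants <- data.frame(id = map$id, chrom = as.integer(map$chrom),
                         pos = as.integer(map$pos),
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = ids, sex = sex, stringsAsFactors = FALSE)
  geno_matrix(calls, variants, samples)
}

#' Write genotypes as PLINK text files (PED/MAP)
#'
#' Inverse of [read_plink_text()]: round-tripping reproduces calls, marker
#' ids and positions exactly. Missing calls are written as "0 0".
#'
#' @param g a [geno_matrix].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(g, prefix) {
  if (n_samples(g) == 0) stop("refusing to write a genotype matrix with no samples")
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  v <- g$variants
  write.table(data.frame(v$chrom, v$id, 0, v$pos),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- n_samples(g); m <- n_variants(g)
  sex_code <- rep(0L, n)
  if (!is.null(g$samples$sex))
    sex_code <- ifelse(is.na(g$samples$sex), 0L,
                       ifelse(g$samples$sex == "female", 2L, 1L))
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (s in seq_len(n)) {
    gt <- character(2 * m)
    cs <- g$calls[s, ]
    i1 <- seq(1, 2 * m, by = 2)
    a <- v$allele_a; b <- v$allele_b
    gt[i1]     <- ifelse(is.na(cs), "0", ifelse(cs >= 1, b, a))
    gt[i1 + 1] <- ifelse(is.na(cs), "0", ifelse(cs == 2, b, a))
    writeLines(paste(c("FAM", g$samples$id[s], "0", "0", sex_code[s], "-9",
                       gt), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a phenotype and covariate table
#'
#' Reads a tab- or comma-separated table with one row per sample. The
#' header must contain an `id` column; trait columns are any of the nine
#' recognised body-measurement/weight traits, covariates are `sex`, `farm`,
#' `birth_year`. All present trait values must be strictly positive.
#'
#' @param path file path.
#' @return A data frame keyed by `id`.
#' @export
read_phenotypes <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  tb <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"id" %in% names(tb)) stop("phenotype table needs an 'id' column")
  if (anyDuplicated(tb$id))
    stop(sprintf("duplicated sample id in phenotype table: %s",
                 tb$id[duplicated(tb$id)][1]))
  traits <- intersect(trait_names(), names(tb))
  for (tr in traits) {
    bad <- which(!is.na(tb[[tr]]) & tb[[tr]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s value at row %d", tr, bad[1]))
  }
  tb
}

#' Recognised phenotype trait names
#'
#' Eight body-measurement traits in cm (wither height, height at hip
#' cross, diagonal body length, chest girth, abdomen circumference, waist
#' angle width, ischial end width, shin circumference) and body weight in
#' kg.
#' @return Character vector of the nine trait column names.
#' @export
trait_names <- function() {
  c("WH", "HHC", "DBL", "CG", "AC", "WAW", "IEW", "SC", "BW")
}

#' Join phenotypes to the samples of a genotype matrix
#'
#' Inner join on sample id; phenotype rows without a genotyped sample are
#' dropped with a message.
#'
#' @param g a [geno_matrix].
#' @param pheno data frame from [read_phenotypes()].
#' @return Data frame in genotype-sample order.
#' @export
match_phenotypes <- function(g, pheno) {
  unmatched <- setdiff(pheno$id, g$samples$id)
  if (length(unmatched))
    message(sprintf("dropping %d phenotype row(s) with no genotyped sample",
                    length(unmatched)))
  idx <- match(g$samples$id, pheno$id)
  out <- pheno[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
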