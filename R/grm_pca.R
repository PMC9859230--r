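#' Centered genotype matrix for GRM construction
#'
#' Z\[s, v\] = call - 2 p_v, with p_v the observed B-allele frequency.
#' Centering at twice the allele frequency makes every column mean zero
#' and absorbs A/B label flips. Monomorphic variants carry no information
#' and are excluded with a warning.
#'
#' @param g a [geno_matrix] with no missing calls.
#' @return List: `Z` (n x m matrix), `freqs` (B-allele frequencies of the
#'   retained variants), `kept` (retained column indices).
#' @export
build_centered_Z <- function(g) {
  if (anyNA(g$calls)) stop("impute missing calls before building Z")
  f <- allele_frequencies(g)
  mono <- f == 0 | f == 1
  if (any(mono))
    warning(sprintf("excluding %d monomorphic variant(s) from Z", sum(mono)))
  keep <- which(!mono)
  Z <- sweep(g$calls[, keep, drop = FALSE], 2, 2 * f[keep], `-`)
  list(Z = Z, freqs = f[keep], kept = keep)
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 sum p_i (1 - p_i)), the first VanRaden method: centered
#' genotypes scaled by the expected total heterozygosity. Diagonal entries
#' average near 1 + f in a population with inbreeding coefficient f.
#'
#' @param Z centered genotype matrix from [build_centered_Z()].
#' @param freqs B-allele frequencies used for centering.
#' @param ids sample ids (defaults to rownames of Z).
#' @param min_markers_warn warn when fewer markers than this support the
#'   matrix (relationship estimates get noisy below a few thousand
#'   markers; default 2500).
#' @return A `grm` object: `values` (n x n), `ids`, `freqs`, `n_markers`.
#' @export
vanraden_grm <- function(Z, freqs, ids = rownames(Z),
                         min_markers_warn = 2500) {
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("zero denominator: no polymorphic markers")
  if (ncol(Z) < min_markers_warn)
    warning(sprintf("GRM built from only %d markers; relationships may be noisy",
                    ncol(Z)))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, ids = ids, freqs = freqs,
                 n_markers = ncol(Z)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("genomic relationship matrix: %d samples, %d markers\n",
              nrow(x$values), x$n_markers))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$values)), mean_kinship(x)))
  invisible(x)
}

#' Convenience: GRM straight from a genotype matrix
#'
#' @param g a [geno_matrix] with no missing calls.
#' @param ... passed to [vanraden_grm()].
#' @return A `grm` object.
#' @export
compute_grm <- function(g, ...) {
  cz <- build_centered_Z(g)
  vanraden_grm(cz$Z, cz$freqs, ids = g$samples$id, ...)
}

#' Mean genomic kinship of the population
#'
#' Arithmetic mean of the strictly off-diagonal entries of G (the
#' relationship scale, default) or of G/2 (the kinship scale).
#'
#' @param G a `grm` object.
#' @param scale `"relationship"` (G) or `"kinship"` (G/2).
#' @return Mean off-diagonal value.
#' @export
mean_kinship <- function(G, scale = c("relationship", "kinship")) {
  scale <- match.arg(scale)
  v <- G$values
  stopifnot(nrow(v) >= 2)
  m <- mean(v[row(v) != col(v)])
  if (scale == "kinship") m / 2 else m
}

#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of G; component j explains lambda_j / sum(lambda+)
#' of the relationship variance (negative eigenvalues are clamped to zero
#' in the denominator but reported raw). Sample scores are the
#' eigenvectors scaled by sqrt(lambda).
#'
#' @param G a `grm` object.
#' @param k number of leading components to return scores for.
#' @return A `grm_pca` list: `eigenvalues`, `scores` (n x k),
#'   `var_frac`, `ids`.
#' @export
grm_pca <- function(G, k = 2) {
  v <- G$values
  if (any(!is.finite(v))) stop("non-finite entries in G")
  stopifnot(k <= nrow(v))
  e <- eigen(v, symmetric = TRUE)
  lam <- e$values
  pos <- pmax(lam, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  rownames(scores) <- G$ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = lam, vectors = e$vectors, scores = scores,
                 var_frac = lam / sum(pos), ids = G$ids),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA of GRM: first %d component(s) explain %.2f%% of variance\n",
              k, 100 * sum(x$var_frac[seq_len(k)])))
  invisible(x)
}

#' Write a GRM in GCTA-style text format
#'
#' Lower-triangle table (i, j, n_markers, value) plus a `.id` file.
#'
#' @param G a `grm` object.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_grm_text <- function(G, prefix) {
  n <- nrow(G$values)
  ij <- which(lower.tri(G$values, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tb <- data.frame(i = ij[, 1], j = ij[, 2], n = G$n_markers,
                   value = G$values[ij])
  grm_path <- paste0(prefix, ".grm.txt")
  id_path <- paste0(prefix, ".grm.id")
  write.table(tb, grm_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame("FAM", G$ids), id_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(c(grm = grm_path, id = id_path))
}
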