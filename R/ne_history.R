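#' Configuration for LD-based Ne estimation
#'
#' @param recomb_rate genome-average recombination rate in cM/Mb
#'   (default 1, the bovine genome-wide average).
#' @param alpha constant term of the Sved-type relation
#'   E[r2] = 1/(alpha + 4 Ne c). The default 2 matches the Hill-Weir
#'   drift-recombination equilibrium 1/(2 + 4 Ne c) for a randomly
#'   mating population without mutation; 1 gives Sved's original form.
#' @param phase_known whether haplotype phase is observed (affects the
#'   finite-sample r2 correction).
#' @param max_generations horizon of the reported trajectory.
#' @param smooth_window rolling-median window over trajectory points
#'   (1 disables smoothing).
#' @param r2_estimator which r2 estimator produced the bins ("em" or
#'   "composite"); sets the finite-sample floor, see [adjust_r2()].
#' @return An `ne_config` list.
#' @export
ne_config <- function(recomb_rate = 1.0, alpha = 2, phase_known = FALSE,
                      max_generations = 200, smooth_window = 5,
                      r2_estimator = c("em", "composite")) {
  stopifnot(recomb_rate > 0, alpha %in% c(1, 2), max_generations >= 1)
  structure(list(recomb_rate = recomb_rate, alpha = alpha,
                 phase_known = phase_known,
                 max_generations = max_generations,
                 smooth_window = smooth_window,
                 r2_estimator = match.arg(r2_estimator)),
            class = "ne_config")
}

#' Physical distance to recombination fraction (Haldane)
#'
#' Map length m = d * rate * 1e-8 Morgans, then Haldane's map function
#' c = (1 - exp(-2 m)) / 2. For small m, c ~ m.
#'
#' @param d physical distance in bp.
#' @param rate recombination rate in cM/Mb.
#' @return Recombination fraction in \[0, 0.5).
#' @export
physical_to_recomb <- function(d, rate = 1.0) {
  stopifnot(all(d >= 0))
  m <- d * rate * 1e-8
  0.5 * (1 - exp(-2 * m))
}

#' Finite-sample correction of mean r2
#'
#' Subtracts the sampling floor of r2 — the LD expected in a finite
#' sample of n diploids even under linkage equilibrium — before the Sved
#' inversion. The floor depends on how r2 was estimated: the EM
#' (maximum-likelihood gamete-frequency) estimator recovers 2n gametes
#' and floors at 1/(2n), the same as truly phased data, whereas the
#' composite genotype-correlation estimator floors at 1/n. Phased input
#' always floors at 1/(2n). The result is clamped at a small positive
#' epsilon.
#'
#' @param mean_r2 observed mean r2.
#' @param n diploid sample count (>= 2).
#' @param phase_known logical; phased input.
#' @param estimator `"em"` (gamete-frequency ML, the package default) or
#'   `"composite"` (genotype correlation).
#' @param eps lower clamp.
#' @return Adjusted r2 > 0.
#' @export
adjust_r2 <- function(mean_r2, n, phase_known = FALSE,
                      estimator = c("em", "composite"), eps = 1e-6) {
  stopifnot(n >= 2)
  estimator <- match.arg(estimator)
  floorv <- if (phase_known || estimator == "em") 1 / (2 * n) else 1 / n
  pmax(mean_r2 - floorv, eps)
}

#' Invert the Sved relation for one distance bin
#'
#' Under drift-recombination equilibrium E\[r2\] = 1/(alpha + 4 Ne c), so
#' Ne = (1/r2 - alpha) / (4 c), reflecting the effective size roughly
#' t = 1/(2 c) generations ago.
#'
#' @param adjusted_r2 floor-corrected mean r2 in (0, 1).
#' @param c recombination fraction in (0, 0.5).
#' @param alpha mating-system constant (1 or 2).
#' @return List `(t, ne, c)`, or NULL (with a warning) when the implied
#'   Ne is non-positive.
#' @export
ne_from_bin <- function(adjusted_r2, c, alpha = 1) {
  stopifnot(adjusted_r2 > 0, adjusted_r2 < 1, c > 0, c < 0.5)
  ne <- (1 / adjusted_r2 - alpha) / (4 * c)
  if (ne <= 0) {
    warning("bin dropped: adjusted r2 implies non-positive Ne")
    return(NULL)
  }
  list(t = 1 / (2 * c), ne = ne, c = c)
}

rolling_median <- function(x, w) {
  if (w <= 1 || length(x) < 2) return(x)
  h <- (w - 1) %/% 2
  vapply(seq_along(x), function(i) {
    median(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}

#' Historical Ne trajectory from an LD-decay curve
#'
#' Converts each non-empty distance bin to a recombination fraction via
#' the Haldane map (bin midpoint), corrects the bin mean r2 for the
#' finite-sample floor, and inverts the Sved relation. One estimate per
#' usable bin, ordered by generations ago (ascending); bins implying
#' t > `max_generations` or a non-positive Ne are dropped. Optional
#' rolling-median smoothing of the Ne series.
#'
#' @param bins data frame from [decay_bins()].
#' @param n diploid sample count behind the r2 estimates.
#' @param cfg an [ne_config()].
#' @return Data frame with `t` (generations ago), `ne`, `c`, `n_pairs`.
#' @export
ne_trajectory <- function(bins, n, cfg = ne_config()) {
  use <- bins[bins$n_pairs > 0 & !is.na(bins$mean_r2), , drop = FALSE]
  if (!nrow(use)) stop("no usable LD bins for Ne estimation")
  mid <- (use$lo + use$hi) / 2
  cc <- physical_to_recomb(mid, cfg$recomb_rate)
  adj <- adjust_r2(use$mean_r2, n, cfg$phase_known, cfg$r2_estimator)
  est <- lapply(seq_len(nrow(use)), function(i) {
    if (adj[i] >= 1 / cfg$alpha) return(NULL)
    e <- suppressWarnings(ne_from_bin(adj[i], cc[i], cfg$alpha))
    if (is.null(e)) return(NULL)
    data.frame(t = e$t, ne = e$ne, c = e$c, n_pairs = use$n_pairs[i])
  })
  est <- do.call(rbind, est)
  if (is.null(est) || !nrow(est)) stop("no usable LD bins for Ne estimation")
  est <- est[est$t <= cfg$max_generations, , drop = FALSE]
  if (!nrow(est)) stop("no bins within the generation horizon")
  est <- est[order(est$t), , drop = FALSE]
  est$ne <- rolling_median(est$ne, cfg$smooth_window)
  rownames(est) <- NULL
  est
}
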