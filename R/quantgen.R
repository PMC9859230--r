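#' Remove phenotype outliers beyond three standard deviations
#'
#' One-pass rule: records with |x - mean| > 3 SD, with mean and SD taken
#' from the full input, are dropped. A zero-SD (constant) vector removes
#' nothing. The pass is not iterated.
#'
#' @param values numeric trait vector.
#' @param ids optional record identifiers.
#' @return List: `values`, `ids`, `kept` (logical over the input),
#'   `n_removed`.
#' @export
remove_outliers <- function(values, ids = seq_along(values)) {
  ok <- !is.na(values)
  stopifnot(sum(ok) >= 3)
  m <- mean(values[ok])
  s <- sd(values[ok])
  keep <- ok & (s == 0 | abs(values - m) <= 3 * s)
  if (!any(keep)) stop("outlier rule removed every record")
  list(values = values[keep], ids = ids[keep], kept = keep,
       n_removed = sum(ok) - sum(keep))
}

#' Fixed-effect incidence matrix from sample covariates
#'
#' Intercept plus treatment-coded sex, farm and birth-year factors.
#' Factors with a single level collapse into the intercept; aliased
#' columns are dropped to restore full column rank (with a message).
#'
#' @param samples data frame with optional `sex`, `farm`, `birth_year`.
#' @return Incidence matrix X with full column rank.
#' @export
build_fixed_design <- function(samples) {
  n <- nrow(samples)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in c("sex", "farm", "birth_year")) {
    if (!v %in% names(samples)) next
    f <- factor(samples[[v]])
    if (nlevels(f) < 2) next
    M <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0(v, levels(f)[-1])
    X <- cbind(X, M)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])
    message(sprintf("dropping %d aliased fixed-effect column(s): %s",
                    length(drop), paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

# Restricted log-likelihood of the rotated one-random-effect model at a
# given variance ratio lambda = sigma_a2 / sigma_e2, with sigma_e2
# profiled out. ystar/Xstar are U'y and U'X for G = U D U'.
reml_loglik_lambda <- function(log10_lambda, ystar, Xstar, d) {
  lambda <- 10^log10_lambda
  n <- length(ystar)
  p <- ncol(Xstar)
  w <- lambda * d + 1
  Xw <- Xstar / w
  XtWiX <- crossprod(Xstar, Xw)
  beta <- solve(XtWiX, crossprod(Xw, ystar))
  r <- ystar - Xstar %*% beta
  rss <- sum(r^2 / w)
  sigma_e2 <- rss / (n - p)
  ld <- determinant(XtWiX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma_e2) + sum(log(w)) +
            as.numeric(ld) + (n - p))
}

# Unprofiled restricted log-likelihood in (sigma_a2, sigma_e2); used for
# the observed-information standard errors.
reml_loglik_varcomp <- function(sigma_a2, sigma_e2, ystar, Xstar, d) {
  n <- length(ystar)
  p <- ncol(Xstar)
  w <- sigma_a2 * d + sigma_e2
  Xw <- Xstar / w
  XtViX <- crossprod(Xstar, Xw)
  beta <- solve(XtViX, crossprod(Xw, ystar))
  r <- ystar - Xstar %*% beta
  ld <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + sum(log(w)) + as.numeric(ld) +
            sum(r^2 / w))
}

#' Genomic REML for a single trait
#'
#' Fits the animal model y = X beta + g + e with g ~ N(0, G sigma_a2) and
#' e ~ N(0, I sigma_e2) by restricted maximum likelihood. Because the
#' model has a single random effect, one eigendecomposition of G
#' diagonalises the covariance: rotating y and X by the eigenvectors
#' reduces REML to a one-dimensional search over the variance ratio
#' lambda = sigma_a2/sigma_e2 (Brent search on log10 lambda in
#' \[-10, 10\], sigma_e2 profiled out). Standard errors come from the
#' observed information of the unprofiled restricted likelihood via the
#' delta method.
#'
#' @param y trait vector (no NAs).
#' @param X fixed-effect incidence matrix from [build_fixed_design()].
#' @param G a `grm` object (or bare symmetric matrix) over the same
#'   samples, in the same order.
#' @param ridge small constant added to the diagonal of G to guard rank
#'   deficiency (default 1e-6).
#' @param bounds search bounds on log10 lambda.
#' @return A `varcomp` list: `sigma_a2`, `sigma_e2`, `h2`, `se_h2`,
#'   `loglik`, `n_used`, `boundary` flag, plus the eigen-rotation pieces
#'   (`ystar`, `Xstar`, `d`) for reuse.
#' @export
reml_fit <- function(y, X, G, ridge = 1e-6, bounds = c(-10, 10)) {
  v <- if (inherits(G, "grm")) G$values else G
  n <- length(y)
  stopifnot(nrow(v) == n, nrow(X) == n, !anyNA(y))
  if (n <= ncol(X) + 1) stop("too few records for REML")
  e <- eigen(v + diag(ridge, n), symmetric = TRUE)
  d <- e$values
  if (sd(d) < 1e-10 * max(abs(d), 1))
    stop("variance components not separable: G is proportional to the identity")
  ystar <- drop(crossprod(e$vectors, y))
  Xstar <- crossprod(e$vectors, X)
  opt <- optimize(reml_loglik_lambda, interval = bounds, maximum = TRUE,
                  tol = 1e-9, ystar = ystar, Xstar = Xstar, d = d)
  ll <- opt$objective
  lambda <- 10^opt$maximum
  boundary <- min(abs(opt$maximum - bounds)) < 1e-3
  if (boundary)
    warning("REML optimum at the variance-ratio boundary; h2 estimate is at its limit")
  # recover sigma_e2 at the optimum
  p <- ncol(Xstar)
  w <- lambda * d + 1
  Xw <- Xstar / w
  beta <- solve(crossprod(Xstar, Xw), crossprod(Xw, ystar))
  sigma_e2 <- sum((ystar - Xstar %*% beta)^2 / w) / (n - p)
  sigma_a2 <- lambda * sigma_e2
  h2 <- heritability(sigma_a2, sigma_e2)
  se_h2 <- reml_se_h2(sigma_a2, sigma_e2, ystar, Xstar, d)
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2,
                 se_h2 = se_h2, loglik = ll, n_used = n,
                 boundary = boundary, lambda = lambda,
                 ystar = ystar, Xstar = Xstar, d = d),
            class = "varcomp")
}

# Delta-method SE of h2 from a central-difference Hessian of the
# unprofiled restricted likelihood.
reml_se_h2 <- function(sigma_a2, sigma_e2, ystar, Xstar, d) {
  f <- function(th) reml_loglik_varcomp(th[1], th[2], ystar, Xstar, d)
  th <- c(sigma_a2, sigma_e2)
  hstep <- pmax(abs(th) * 1e-4, 1e-8)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0)
    ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- (f(pmax(th + ei + ej, 1e-12)) - f(pmax(th + ei - ej, 1e-12)) -
                  f(pmax(th - ei + ej, 1e-12)) + f(pmax(th - ei - ej, 1e-12))) /
      (4 * hstep[i] * hstep[j])
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) < 0)) return(NA_real_)
  s <- sigma_a2 + sigma_e2
  grad <- c(sigma_e2, -sigma_a2) / s^2
  sqrt(drop(t(grad) %*% V %*% grad))
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (SE %.3f)\n",
              x$sigma_a2, x$sigma_e2, x$h2,
              ifelse(is.na(x$se_h2), NaN, x$se_h2)))
  if (isTRUE(x$boundary)) cat("  note: optimum at the search boundary\n")
  invisible(x)
}

#' Restricted log-likelihood at a given variance ratio
#'
#' Evaluates the profiled restricted likelihood of a fitted model at an
#' arbitrary log10 variance ratio; used to check the optimizer against a
#' grid.
#'
#' @param fit a `varcomp` object from [reml_fit()].
#' @param log10_lambda scalar or vector of log10(sigma_a2/sigma_e2).
#' @return Restricted log-likelihood value(s).
#' @export
reml_profile <- function(fit, log10_lambda) {
  vapply(log10_lambda, reml_loglik_lambda, numeric(1),
         ystar = fit$ystar, Xstar = fit$Xstar, d = fit$d)
}

#' Narrow-sense heritability from variance components
#'
#' h2 = sigma_a2 / (sigma_a2 + sigma_e2): the proportion of phenotypic
#' variance attributable to additive genetic variance.
#'
#' @param sigma_a2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (> 0 unless sigma_a2 > 0).
#' @return h2 in \[0, 1\].
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0)
  if (sigma_a2 + sigma_e2 == 0) stop("both variance components are zero")
  sigma_a2 / (sigma_a2 + sigma_e2)
}

#' Coefficient of variation of a trait
#'
#' CV% = 100 SD/mean with the sample (n-1) standard deviation.
#'
#' @param values positive trait vector.
#' @return List: `mean`, `sd`, `cv_percent`.
#' @export
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (m <= 0) stop("CV undefined for non-positive mean")
  s <- sd(values)
  list(mean = m, sd = s, cv_percent = 100 * s / m)
}

#' F-tests of the fixed effects on one trait
#'
#' Sequential ANOVA of an ordinary least-squares fit of the trait on sex,
#' farm and birth year; a quick screen of which covariates matter.
#'
#' @param values trait vector.
#' @param samples covariate data frame aligned with `values`.
#' @return ANOVA table.
#' @export
fixed_effects_ftest <- function(values, samples) {
  covs <- intersect(c("sex", "farm", "birth_year"), names(samples))
  covs <- covs[vapply(covs, function(v) length(unique(samples[[v]])) > 1,
                      logical(1))]
  if (!length(covs)) stop("no multi-level covariates to test")
  df <- cbind(data.frame(y = values), samples[covs])
  for (v in covs) df[[v]] <- factor(df[[v]])
  anova(lm(as.formula(paste("y ~", paste(covs, collapse = " + "))), df))
}

#' Fit genomic heritability for every trait in a phenotype table
#'
#' Per trait: drop missing records, apply the three-SD outlier rule,
#' build the fixed-effect design on the retained samples, subset the GRM,
#' and fit REML. Fixed effects are absorbed inside the REML model rather
#' than pre-corrected; set `precorrect = TRUE` to instead fit REML on
#' intercept-only OLS residuals.
#'
#' @param pheno data frame in genotype-sample order (see
#'   [match_phenotypes()]).
#' @param G a `grm` over the same samples (by id).
#' @param traits trait columns to fit (default: all recognised present).
#' @param precorrect pre-adjust phenotypes by OLS instead of joint
#'   fitting.
#' @param ... passed to [reml_fit()].
#' @return Data frame: trait, n, sigma_a2, sigma_e2, h2, se_h2, loglik,
#'   cv_percent.
#' @export
fit_traits <- function(pheno, G, traits = NULL, precorrect = FALSE, ...) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(pheno))
  rows <- lapply(traits, function(tr) {
    ok <- !is.na(pheno[[tr]])
    cl <- remove_outliers(pheno[[tr]][ok], pheno$id[ok])
    idx <- match(cl$ids, G$ids)
    stopifnot(!anyNA(idx))
    Gs <- structure(list(values = G$values[idx, idx, drop = FALSE],
                         ids = G$ids[idx], freqs = G$freqs,
                         n_markers = G$n_markers), class = "grm")
    samp <- pheno[ok, , drop = FALSE][cl$kept, , drop = FALSE]
    X <- build_fixed_design(samp)
    y <- cl$values
    if (precorrect) {
      y <- y - X %*% qr.solve(X, y) + mean(y)
      X <- matrix(1, length(y), 1)
    }
    fit <- reml_fit(y, X, Gs, ...)
    cv <- compute_cv(cl$values)
    data.frame(trait = tr, n = fit$n_used, n_outliers = cl$n_removed,
               sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
               h2 = fit$h2, se_h2 = fit$se_h2, loglik = fit$loglik,
               cv_percent = cv$cv_percent,
               boundary = fit$boundary)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
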