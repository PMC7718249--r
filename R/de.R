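#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per gene, on normalized counts, the dispersion is estimated as
#' `alpha = max(alpha_min, (v - m) / m^2)` where `v` is the pooled
#' within-group variance over the two contrast groups and `m` the mean over
#' all contrast samples; `alpha_min = 1e-8`. Genes at or below the Poisson
#' limit (variance <= mean) land on the floor.
#'
#' @param counts a [count_matrix()] or counts matrix.
#' @param size_factors per-sample size factors.
#' @param sheet sample sheet.
#' @param contrast character pair `c(A, B)` of group labels; both groups
#'   must have at least 2 samples.
#' @return named per-gene dispersion vector.
#' @export
estimate_dispersions <- function(counts, size_factors, sheet, contrast) {
  m <- .counts_of(counts)
  sheet <- .align_sheet(m, sheet)
  idx <- .contrast_index(sheet, contrast)
  norm <- sweep(m, 2L, size_factors, `/`)
  a <- norm[, idx$A, drop = FALSE]
  b <- norm[, idx$B, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  varA <- apply(a, 1L, stats::var)
  varB <- apply(b, 1L, stats::var)
  v <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
  mu <- rowMeans(cbind(a, b))
  alpha <- ifelse(mu > 0, (v - mu) / mu^2, 0)
  pmax(stats::setNames(alpha, rownames(m)), 1e-8)
}

.contrast_index <- function(sheet, contrast) {
  if (length(contrast) != 2L || contrast[1L] == contrast[2L])
    .stopf("contrast must name two distinct groups")
  g <- as.character(sheet$group)
  A <- which(g == contrast[1L]); B <- which(g == contrast[2L])
  if (length(A) < 2L || length(B) < 2L)
    .stopf("contrast group '%s' has fewer than 2 samples",
           contrast[c(length(A) < 2L, length(B) < 2L)][1L])
  list(A = A, B = B)
}

#' Negative-binomial Wald test between two groups
#'
#' Per gene, fits the log-linear model `mu_ij = s_j * exp(b0 + b1 * [j in A])`
#' at fixed gene-wise dispersion by iteratively reweighted least squares
#' (Fisher scoring), vectorized across genes. `log2fc = b1 / ln 2`; the
#' standard error comes from the Fisher information; the Wald statistic is
#' referred to a standard normal, two-sided. No fold-change shrinkage,
#' independent filtering or outlier handling is applied. Genes that fail to
#' converge (or have zero mean in a contrast group) get `p = NA` and are
#' excluded from the Benjamini-Hochberg adjustment.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions per-gene dispersion vector (default:
#'   [estimate_dispersions()]).
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient update.
#' @return a `de_result` data.frame with columns `gene_id`, `base_mean`
#'   (mean normalized reads over contrast samples), `mean_<A>`, `mean_<B>`,
#'   `log2fc` (positive = up in A), `se`, `stat`, `p`, `padj`; the contrast
#'   is stored as an attribute.
#' @export
nb_wald_test <- function(counts, size_factors, sheet, contrast,
                         dispersions = NULL, maxit = 50L, tol = 1e-8) {
  m <- .counts_of(counts)
  sheet <- .align_sheet(m, sheet)
  idx <- .contrast_index(sheet, contrast)
  if (length(size_factors) != ncol(m)) .stopf("one size factor per sample required")
  dispersions <- dispersions %||%
    estimate_dispersions(m, size_factors, sheet, contrast)
  if (length(dispersions) == 1L) dispersions <- rep(dispersions, nrow(m))

  cols <- c(idx$A, idx$B)
  y <- m[, cols, drop = FALSE]
  s <- size_factors[cols]
  aind <- rep(c(1, 0), c(length(idx$A), length(idx$B)))  # indicator of group A
  off <- log(s)
  G <- nrow(y)

  norm <- sweep(y, 2L, s, `/`)
  meanA <- rowMeans(norm[, aind == 1, drop = FALSE])
  meanB <- rowMeans(norm[, aind == 0, drop = FALSE])
  base_mean <- rowMeans(norm)
  estimable <- meanA > 0 & meanB > 0

  beta0 <- log(pmax(meanB, 1e-8))
  beta1 <- log(pmax(meanA, 1e-8)) - beta0
  active <- estimable
  converged <- !estimable  # non-estimable genes never enter the loop
  converged[] <- FALSE
  alpha <- dispersions

  for (it in seq_len(maxit)) {
    if (!any(active)) break
    eta <- outer(beta0[active], rep(1, length(cols))) +
      outer(beta1[active], aind) +
      matrix(off, sum(active), length(cols), byrow = TRUE)
    mu <- exp(eta)
    w <- mu / (1 + alpha[active] * mu)
    z <- (eta - matrix(off, sum(active), length(cols), byrow = TRUE)) +
      (y[active, , drop = FALSE] - mu) / mu
    sw <- rowSums(w)
    swa <- rowSums(w * rep(aind, each = sum(active)))
    b1v <- rowSums(w * z)
    b2v <- rowSums(w * z * rep(aind, each = sum(active)))
    det <- swa * (sw - swa)
    new0 <- (swa * b1v - swa * b2v) / det
    new1 <- (sw * b2v - swa * b1v) / det
    ## solve [sw swa; swa swa] beta = [b1v; b2v]
    new0 <- (swa * b1v - swa * b2v) / det  # = (A22*b1 - A12*b2)/det with A22=A12=swa
    delta0 <- new0 - beta0[active]
    delta1 <- new1 - beta1[active]
    ok <- is.finite(new0) & is.finite(new1)
    step <- pmax(abs(delta0), abs(delta1))
    beta0[active][ok] <- new0[ok]
    beta1[active][ok] <- new1[ok]
    done <- ok & step < tol
    diverged <- !ok
    conv_idx <- which(active)[done]
    converged[conv_idx] <- TRUE
    active[which(active)[done | diverged]] <- FALSE
  }

  ## Fisher information at the converged estimate
  eta <- outer(beta0, rep(1, length(cols))) + outer(beta1, aind) +
    matrix(off, G, length(cols), byrow = TRUE)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  sw <- rowSums(w)
  swa <- rowSums(w * rep(aind, each = G))
  det <- swa * (sw - swa)
  se_b1 <- sqrt(sw / det)

  usable <- estimable & converged & is.finite(se_b1) & se_b1 > 0
  n_failed <- sum(estimable & !usable)
  if (n_failed > 0L)
    .warnf("%d gene(s) did not converge in the NB fit; p set to NA", n_failed)

  log2fc <- beta1 / log(2)
  se <- se_b1 / log(2)
  stat <- beta1 / se_b1
  p <- 2 * stats::pnorm(-abs(stat))
  log2fc[!usable] <- NA_real_; se[!usable] <- NA_real_
  stat[!usable] <- NA_real_; p[!usable] <- NA_real_

  res <- data.frame(gene_id = rownames(m), base_mean = base_mean,
                    meanA, meanB,
                    log2fc = log2fc, se = se, stat = stat, p = p,
                    padj = adjust_bh(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  names(res)[3:4] <- paste0("mean_", contrast)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min(1, min_{k >= i} m * p_(k) / k)` over the `m` non-missing
#' p-values, restored to input order; `NA` p-values stay `NA` and do not
#' count toward `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[order(o)]
  out[ok] <- adj
  out
}

#' Thresholds defining a differentially expressed gene
#'
#' Defaults follow the strict DEG definition used throughout the package:
#' |log2FC| > 2, BH-adjusted p < 0.05, and mean normalized reads > 10 in
#' the upregulated group. All comparisons are strict.
#'
#' @param log2fc_min positive log2 fold-change bound (exclusive).
#' @param padj_max adjusted-p bound in (0, 1) (exclusive).
#' @param min_mean_norm minimum mean normalized reads in the upregulated
#'   group (exclusive).
#' @return a `deg_thresholds` list.
#' @export
deg_thresholds <- function(log2fc_min = 2, padj_max = 0.05, min_mean_norm = 10) {
  if (log2fc_min <= 0) .stopf("log2fc_min must be > 0")
  if (padj_max <= 0 || padj_max >= 1) .stopf("padj_max must be in (0, 1)")
  if (min_mean_norm < 0) .stopf("min_mean_norm must be >= 0")
  structure(list(log2fc_min = log2fc_min, padj_max = padj_max,
                 min_mean_norm = min_mean_norm), class = "deg_thresholds")
}

#' Call differentially expressed genes from a Wald-test result
#'
#' A gene is up in A iff `log2fc > log2fc_min`, `padj < padj_max` and the
#' mean normalized reads in A exceed `min_mean_norm`; symmetrically for up
#' in B with `log2fc < -log2fc_min` and the mean in B. The two sets are
#' disjoint by construction.
#'
#' @param result a `de_result` from [nb_wald_test()].
#' @param thresholds a [deg_thresholds()].
#' @return list with elements `up_in_A` and `up_in_B`, each a character
#'   vector of gene ids carrying `contrast`, `direction` and `thresholds`
#'   attributes.
#' @export
call_degs <- function(result, thresholds = deg_thresholds()) {
  contrast <- attr(result, "contrast")
  mA <- result[[paste0("mean_", contrast[1L])]]
  mB <- result[[paste0("mean_", contrast[2L])]]
  ok <- !is.na(result$padj)
  upA <- ok & result$log2fc > thresholds$log2fc_min &
    result$padj < thresholds$padj_max & mA > thresholds$min_mean_norm
  upB <- ok & result$log2fc < -thresholds$log2fc_min &
    result$padj < thresholds$padj_max & mB > thresholds$min_mean_norm
  mk <- function(genes, direction)
    structure(genes, contrast = contrast, direction = direction,
              thresholds = thresholds)
  list(up_in_A = mk(result$gene_id[upA], "up_in_A"),
       up_in_B = mk(result$gene_id[upB], "up_in_B"))
}
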