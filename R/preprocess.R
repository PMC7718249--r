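#' Read a featureCounts-style counts table
#'
#' Parses the tab-separated dialect written by featureCounts (and by
#' [write_fixture()]): optional leading comment lines starting with `#`, a
#' header row `Geneid  Chr  Start  End  Strand  Length  <sample>...`, then
#' one row per gene. Positional columns are kept as opaque annotation.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix()] with genes in file order.
#' @details Duplicate gene ids, ragged rows and non-integer counts raise a
#'   parse error naming the offending line number (1-based, counting every
#'   physical line of the file).
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) .stopf("counts file not found: %s", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) .stopf("counts file %s has no header row", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  fixed <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  if (length(header) < 6L || !identical(header[1:6], fixed))
    .stopf("counts file %s: expected header starting '%s'", path,
           paste(fixed, collapse = "\t"))
  samples <- header[-(1:6)]
  body <- lines[-1L]; body_no <- lineno[-1L]
  if (!length(body)) {
    m <- matrix(0, 0L, length(samples),
                dimnames = list(character(), samples))
    return(count_matrix(m, numeric(0)))
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  bad <- which(widths != length(header))
  if (length(bad))
    .stopf("counts file %s: line %d has %d fields, expected %d",
           path, body_no[bad[1L]], widths[bad[1L]], length(header))
  flat <- matrix(unlist(cells), nrow = length(header))
  gene_ids <- flat[1L, ]
  if (anyDuplicated(gene_ids)) {
    d <- which(duplicated(gene_ids))[1L]
    .stopf("counts file %s: line %d repeats gene id '%s'",
           path, body_no[d], gene_ids[d])
  }
  lens <- suppressWarnings(as.numeric(flat[6L, ]))
  if (anyNA(lens) || any(lens <= 0))
    .stopf("counts file %s: line %d has invalid feature length",
           path, body_no[which(is.na(lens) | lens <= 0)[1L]])
  raw <- flat[-(1:6), , drop = FALSE]
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  badcell <- is.na(num) | num < 0 | num != floor(num)
  if (any(badcell)) {
    badrow <- which(colSums(badcell) > 0)[1L]  # column of `num` = file row
    .stopf("counts file %s: line %d has non-integer count '%s'",
           path, body_no[badrow], raw[which(badcell[, badrow])[1L], badrow])
  }
  counts <- t(num)
  dimnames(counts) <- list(gene_ids, samples)
  ann <- data.frame(Chr = flat[2L, ], Start = flat[3L, ], End = flat[4L, ],
                    Strand = flat[5L, ], stringsAsFactors = FALSE)
  count_matrix(counts, lens, ann)
}

#' Read a sample sheet CSV
#'
#' Expects a header `sample_id,group[,batch][,sex][,year]`; empty optional
#' fields become `NA`.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `sample_id`, `group`, `batch`, `sex`,
#'   `year`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .stopf("sample sheet not found: %s", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("sample_id", "group") %in% names(sheet)))
    .stopf("sample sheet %s must have columns sample_id and group", path)
  for (col in c("batch", "sex", "year")) if (is.null(sheet[[col]])) sheet[[col]] <- NA
  sheet$year <- suppressWarnings(as.integer(sheet$year))
  sheet[, c("sample_id", "group", "batch", "sex", "year")]
}

#' Remove genes with zero mean raw counts in any group
#'
#' A gene is retained iff in every group the mean of its raw counts over
#' that group's samples is > 0 — equivalently, iff it has at least one
#' nonzero count within every group. Applied to raw counts before
#' normalization; gene order is preserved.
#'
#' @param counts a [count_matrix()] (or plain matrix with dimnames).
#' @param sheet sample sheet assigning each sample to a group.
#' @return the filtered [count_matrix()].
#' @export
filter_zero_mean_genes <- function(counts, sheet) {
  m <- .counts_of(counts)
  sheet <- .align_sheet(m, sheet)
  idx <- .group_index(sheet)
  keep <- rep(TRUE, nrow(m))
  for (g in names(idx))
    keep <- keep & rowSums(m[, idx[[g]], drop = FALSE] > 0) > 0L
  if (!any(keep) && nrow(m) > 0L)
    .warnf("every gene has zero mean counts in some group; empty matrix returned")
  if (inherits(counts, "count_matrix")) counts[keep, ] else m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over reference genes of the ratio
#' of the sample's count to the gene's geometric mean across samples;
#' reference genes are those with positive counts in every sample. Factors
#' are not rescaled afterwards, so the normalized scale (and the
#' "mean normalized reads > 10" DEG filter that depends on it) is pure
#' median-of-ratios.
#'
#' When no gene is positive in all samples, a pseudo-reference fallback is
#' used with a warning: each gene's geometric mean is taken over its
#' positive counts only, and each sample's median ratio runs over the genes
#' it has positive counts for.
#'
#' @param counts a [count_matrix()] or plain counts matrix.
#' @return named positive numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(c(2, 8, 4, 16), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' round(estimate_size_factors(m), 3)  # 0.707, 1.414
#' @export
estimate_size_factors <- function(counts) {
  m <- .counts_of(counts)
  if (ncol(m) == 0L) .stopf("no samples")
  logm <- log(m)
  loggeo <- rowMeans(logm)
  usable <- is.finite(loggeo)
  if (any(usable)) {
    sf <- apply(logm[usable, , drop = FALSE], 2L, function(lc) exp(stats::median(lc - loggeo[usable])))
  } else {
    pos_any <- rowSums(m > 0) > 0L
    if (!any(pos_any))
      .stopf("size-factor estimation failed: no gene has a positive count; cannot form a reference")
    .warnf("no gene is positive in all samples; using pseudo-reference over positive counts")
    logm_pos <- logm
    logm_pos[!is.finite(logm_pos)] <- NA
    loggeo_pos <- rowMeans(logm_pos, na.rm = TRUE)
    sf <- apply(logm_pos[pos_any, , drop = FALSE], 2L, function(lc) {
      r <- lc - loggeo_pos[pos_any]
      r <- r[is.finite(r)]
      if (!length(r)) .stopf("size-factor estimation failed: a sample shares no positive gene with the reference")
      exp(stats::median(r))
    })
  }
  if (any(!is.finite(sf) | sf <= 0))
    .stopf("size-factor estimation produced a non-positive factor")
  stats::setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor and forms
#' `log2(normalized + pseudocount)` expression values.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param size_factors positive factors, one per sample (default: estimated
#'   by [estimate_size_factors()]).
#' @param pseudocount pseudocount for the log transform (default 1).
#' @return an object of class `norm_matrix`: list with `norm` (normalized
#'   counts), `log2` (log expression), `size_factors`, `pseudocount`.
#' @export
normalize_counts <- function(counts, size_factors = NULL, pseudocount = 1) {
  m <- .counts_of(counts)
  size_factors <- size_factors %||% estimate_size_factors(m)
  if (length(size_factors) != ncol(m))
    .stopf("need one size factor per sample (%d given, %d samples)",
           length(size_factors), ncol(m))
  if (any(size_factors <= 0)) .stopf("size factors must be positive")
  if (pseudocount <= 0) .stopf("pseudocount must be positive")
  norm <- sweep(m, 2L, size_factors, `/`)
  structure(list(norm = norm, log2 = log2(norm + pseudocount),
                 size_factors = stats::setNames(as.numeric(size_factors), colnames(m)),
                 pseudocount = pseudocount),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d samples (pseudocount %g)\n",
              nrow(x$norm), ncol(x$norm), x$pseudocount))
  invisible(x)
}

#' Transcripts per million from counts and feature lengths
#'
#' Per sample, count rates `K_g / L_g` are rescaled to sum to 1e6. An
#' all-zero sample column yields an all-zero TPM column with a warning.
#'
#' @param counts a [count_matrix()] carrying feature lengths, or a plain
#'   matrix together with `lengths`.
#' @param lengths feature lengths in bp (taken from the `count_matrix` when
#'   omitted).
#' @return numeric matrix of TPM values, same dimnames as the counts.
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  m <- .counts_of(counts)
  lengths <- lengths %||% .lengths_of(counts)
  if (is.null(lengths)) .stopf("feature lengths required for TPM")
  if (length(lengths) != nrow(m) || any(lengths <= 0))
    .stopf("need one positive length per gene")
  rate <- m / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    .warnf("sample(s) with no counts get all-zero TPM: %s",
           paste(colnames(m)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2L, tot, `/`) * 1e6
}

#' Remove batch effects from log expression by linear-model residualization
#'
#' Per gene, ordinary least squares is fitted on a design of group
#' indicators (protected) plus reference-coded batch indicators, and only
#' the fitted batch component is subtracted. With balanced batches the
#' group-mean structure is preserved exactly; a planted additive batch
#' shift is recovered to numerical precision. With a single batch (or no
#' batch column) the matrix is returned unchanged.
#'
#' @param log_expr genes x samples matrix of log expression.
#' @param sheet sample sheet with `group` and `batch` columns.
#' @return matrix of the same shape with the batch component removed.
#' @export
remove_batch_effect <- function(log_expr, sheet) {
  log_expr <- as.matrix(log_expr)
  sheet <- .align_sheet(log_expr, sheet)
  batch <- sheet$batch
  if (all(is.na(batch)) || length(unique(batch)) < 2L) return(log_expr)
  if (anyNA(batch)) .stopf("batch labels missing for sample(s): %s",
                           paste(sheet$sample_id[is.na(batch)], collapse = ", "))
  group <- factor(sheet$group)
  batchf <- factor(batch)
  Xg <- stats::model.matrix(~ 0 + group)
  Xb <- stats::model.matrix(~batchf)[, -1L, drop = FALSE]
  X <- cbind(Xg, Xb)
  if (qr(X)$rank < ncol(X)) {
    tab <- table(group, batchf)
    .stopf("batch is confounded with group (design rank-deficient); group x batch table: %s",
           paste(utils::capture.output(print(tab)), collapse = " | "))
  }
  fit <- stats::lm.fit(X, t(log_expr))
  coef_b <- fit$coefficients[ncol(Xg) + seq_len(ncol(Xb)), , drop = FALSE]
  log_expr - t(Xb %*% coef_b)
}

#' Principal component analysis of samples
#'
#' Gene-centered PCA by singular value decomposition, genes as features,
#' no unit-variance scaling.
#'
#' @param log_expr genes x samples matrix.
#' @param n_components number of components to return;
#'   at most `min(genes, samples - 1)`.
#' @return list with `scores` (samples x components), `var_explained`
#'   (fraction of total variance per returned component, non-increasing)
#'   and `sdev` (all singular standard deviations).
#' @export
pca_samples <- function(log_expr, n_components = 2L) {
  log_expr <- as.matrix(log_expr)
  n <- ncol(log_expr)
  if (n < 2L) .stopf("PCA needs at least 2 samples")
  max_comp <- min(nrow(log_expr), n - 1L)
  if (n_components > max_comp)
    .stopf("n_components (%d) exceeds min(genes, samples - 1) = %d",
           n_components, max_comp)
  pr <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE)
  varfrac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_components), drop = FALSE],
       var_explained = varfrac[seq_len(n_components)],
       sdev = pr$sdev)
}
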