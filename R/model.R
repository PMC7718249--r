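#' Fit the 30-gene nearest-centroid tumor classifier
#'
#' Runs the full analysis on a counts matrix and sample sheet: group-wise
#' zero-mean gene filtering, median-of-ratios size factors, normalization,
#' optional batch-effect removal of the log expression used by the
#' classifier (the differential-expression stage always sees raw counts),
#' PCA, the three pairwise negative-binomial Wald contrasts, strict DEG
#' calling, group-specific sets by overlap of the pairwise upregulated
#' sets, selection of the top `n_top` markers per group, leave-one-out
#' centroid correlations, diagonal-distance scores with SD-based cutoffs,
#' per-sample predictions and the performance report.
#'
#' @param counts a [count_matrix()] (or counts matrix with dimnames).
#' @param sheet sample sheet with `sample_id`, `group` and optionally
#'   `batch`; every group needs at least 2 samples.
#' @param groups ordered group labels; the order fixes the two score axes
#'   (group1 vs group2, group2 vs group3) and the tie priority. Default
#'   `c("SCC", "Pap", "Ctrl")`.
#' @param thresholds DEG thresholds, a [deg_thresholds()].
#' @param n_top markers per group (default 10).
#' @param correlation_scale expression scale for the Pearson correlations:
#'   `"log2norm"` (default) or `"norm"`.
#' @param cutoff_multiplier multiplier `c` for the SD-based confidence
#'   cutoffs.
#' @param pseudocount pseudocount of the log transform.
#' @param batch_correct remove batch effects from the classifier/PCA log
#'   expression when batch labels are present (default TRUE).
#' @param pad when a group's specific set holds fewer than `n_top` genes,
#'   pad its block with the overall highest-expressed remaining genes so the
#'   panel keeps its full size (default TRUE; a warning reports any
#'   padding). Padding is label-agnostic by design, so it cannot leak group
#'   information into the leave-one-out evaluation. With `pad = FALSE` short
#'   blocks are kept as they are.
#' @return an object of class `mace_classifier`; see Details.
#' @details The returned object contains `panel` (marker panel with a
#'   `source` column: `"specific"` or `"padded"`), `de` (named list of the
#'   three `de_result`s), `specific_sets`, `venn` (pairwise up-set
#'   partitions), `loo` (per-sample table with correlations, scores,
#'   prediction, confidence), `cutoffs`, `report` (a
#'   [classifier_report()]), `pca`, `size_factors`, `centroids` (full-data,
#'   used by [predict.mace_classifier()]) and the call parameters.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 400, seed = 3))
#' fit <- mace_classifier(sim$counts, sim$sheet)
#' fit
#' summary(fit)
#' @export
mace_classifier <- function(counts, sheet,
                            groups = c("SCC", "Pap", "Ctrl"),
                            thresholds = deg_thresholds(),
                            n_top = 10L,
                            correlation_scale = c("log2norm", "norm"),
                            cutoff_multiplier = 1,
                            pseudocount = 1,
                            batch_correct = TRUE,
                            pad = TRUE) {
  correlation_scale <- match.arg(correlation_scale)
  m <- .counts_of(counts)
  sheet <- .align_sheet(m, sheet)
  idx <- .group_index(sheet, groups)
  if (length(groups) != 3L)
    .stopf("the classifier is defined for exactly 3 groups")
  small <- names(idx)[lengths(idx) < 2L]
  if (length(small))
    .stopf("group '%s' has %d sample(s); at least 2 are required",
           small[1L], length(idx[[small[1L]]]))

  filtered <- filter_zero_mean_genes(counts, sheet)
  fm <- .counts_of(filtered)
  if (nrow(fm) == 0L) .stopf("no genes left after the zero-mean-group filter")
  size_factors <- estimate_size_factors(fm)
  normalized <- normalize_counts(filtered, size_factors, pseudocount)

  expr_log <- normalized$log2
  batch_applied <- FALSE
  if (batch_correct && !all(is.na(sheet$batch)) &&
      length(unique(stats::na.omit(sheet$batch))) > 1L) {
    expr_log <- remove_batch_effect(expr_log, sheet)
    batch_applied <- TRUE
  }
  pca <- pca_samples(expr_log, n_components = min(2L, ncol(fm) - 1L))

  ## three pairwise contrasts on raw filtered counts
  pairs <- list(c(groups[1L], groups[3L]),
                c(groups[2L], groups[3L]),
                c(groups[1L], groups[2L]))
  de <- lapply(pairs, function(ct)
    nb_wald_test(fm, size_factors, sheet, ct))
  names(de) <- vapply(pairs, paste, "", collapse = "_vs_")

  up_sets <- stats::setNames(lapply(groups, function(g) list()), groups)
  for (k in seq_along(pairs)) {
    ct <- pairs[[k]]
    degs <- call_degs(de[[k]], thresholds)
    up_sets[[ct[1L]]][[ct[2L]]] <- degs$up_in_A
    up_sets[[ct[2L]]][[ct[1L]]] <- degs$up_in_B
  }
  specific <- group_specific_genes(up_sets, groups)
  venn <- list()
  venn[[paste0(groups[1L], "_", groups[2L], "_up_vs_", groups[3L])]] <-
    venn_partition(up_sets[[groups[1L]]][[groups[3L]]],
                   up_sets[[groups[2L]]][[groups[3L]]])
  for (g in groups) {
    others <- setdiff(groups, g)
    venn[[paste0(g, "_specific")]] <-
      venn_partition(up_sets[[g]][[others[1L]]], up_sets[[g]][[others[2L]]])
  }

  panel <- select_top_markers(specific, normalized, sheet, n_top)
  panel$source <- rep("specific", nrow(panel))
  if (pad) panel <- .pad_panel(panel, normalized, sheet, groups, n_top)

  profile_input <- if (batch_applied && correlation_scale == "log2norm")
    expr_log else normalized
  profiles <- expression_profile(profile_input, panel, scale = correlation_scale)
  cors <- loo_correlations(profiles, sheet)
  scores <- diagonal_scores(cors, groups)
  cutoffs <- determine_cutoffs(scores, c = cutoff_multiplier)
  loo <- classify_samples(scores, cutoffs)
  report <- classifier_report(loo, groups)

  structure(list(panel = panel, de = de, specific_sets = specific,
                 venn = venn, loo = loo, cutoffs = cutoffs, report = report,
                 pca = pca, size_factors = size_factors,
                 centroids = group_centroids(profiles, sheet),
                 sheet = sheet, groups = groups, thresholds = thresholds,
                 n_top = as.integer(n_top),
                 correlation_scale = correlation_scale,
                 cutoff_multiplier = cutoff_multiplier,
                 pseudocount = pseudocount,
                 batch_corrected = batch_applied,
                 n_genes_filtered = nrow(fm),
                 ref_log_geomeans = .ref_log_geomeans(fm),
                 de_engine = "maceclass NB-Wald (median-of-ratios, MoM dispersion, no shrinkage)",
                 call = match.call()),
            class = "mace_classifier")
}

## Reference log geometric means over genes positive in all training samples,
## kept so predict() can compute frozen median-of-ratios factors for new data.
.ref_log_geomeans <- function(m) {
  lg <- rowMeans(log(m))
  lg[is.finite(lg)]
}

## Fill short panel blocks with the overall highest-expressed remaining genes.
## Padding is deliberately label-agnostic (ranked by the mean over ALL
## samples): ranking within the group would make the padded genes carry label
## information and leak through the fixed-panel leave-one-out evaluation.
.pad_panel <- function(panel, normalized, sheet, groups, n_top) {
  norm <- normalized$norm
  for (g in groups) {
    block <- panel[panel$group == g, , drop = FALSE]
    need <- n_top - nrow(block)
    if (need <= 0L) next
    pool <- setdiff(rownames(norm), panel$gene_id)
    mn <- rowMeans(norm[pool, , drop = FALSE])
    ord <- order(-mn, pool)
    add <- utils::head(pool[ord], need)
    if (!length(add)) next
    .warnf("padding group %s panel block with %d overall highest-expressed gene(s)",
           g, length(add))
    extra <- data.frame(group = rep(g, length(add)),
                        rank = nrow(block) + seq_along(add),
                        gene_id = add, mean_norm = unname(mn[match(add, pool)]),
                        source = "padded", stringsAsFactors = FALSE)
    ## insert after the block, keeping the group block order
    pieces <- split(panel, factor(panel$group, groups))
    pieces[[g]] <- rbind(pieces[[g]], extra)
    panel <- do.call(rbind, pieces)
    rownames(panel) <- NULL
  }
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @export
print.mace_classifier <- function(x, ...) {
  cat("Nearest-centroid expression classifier\n")
  cat(sprintf("  groups: %s (n = %s)\n", paste(x$groups, collapse = "/"),
              paste(table(factor(x$sheet$group, x$groups)), collapse = "/")))
  cat(sprintf("  genes after group-zero filter: %d\n", x$n_genes_filtered))
  cat(sprintf("  marker panel: %d genes (%d specific, %d padded)\n",
              nrow(x$panel), sum(x$panel$source == "specific"),
              sum(x$panel$source == "padded")))
  cat(sprintf("  LOO accuracy: %.1f%%  macro AUC: %.2f\n",
              100 * x$report$accuracy, x$report$auc$macro))
  invisible(x)
}

#' @export
summary.mace_classifier <- function(object, ...) {
  structure(list(fit = object), class = "summary.mace_classifier")
}

#' @export
print.summary.mace_classifier <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nDEG counts per contrast (up in first / up in second):\n")
  for (nm in names(f$de)) {
    ct <- attr(f$de[[nm]], "contrast")
    degs <- call_degs(f$de[[nm]], f$thresholds)
    cat(sprintf("  %-14s %d / %d\n", nm, length(degs$up_in_A), length(degs$up_in_B)))
  }
  cat("\nGroup-specific genes:",
      paste(sprintf("%s=%d", names(f$specific_sets), lengths(f$specific_sets)),
            collapse = ", "), "\n\n")
  print(f$report)
  invisible(x)
}

#' Marker-panel centroids of the fitted classifier
#'
#' @param object a `mace_classifier`.
#' @param ... unused.
#' @return panel-genes x groups matrix of full-data centroid expression on
#'   the classifier's correlation scale.
#' @export
coef.mace_classifier <- function(object, ...) object$centroids

#' Classify new samples with a fitted classifier
#'
#' New counts are normalized by frozen median-of-ratios factors (median
#' ratio to the training reference geometric means), profiled over the
#' fitted marker panel on the training scale, and correlated to the
#' full-data training centroids. No batch correction is applied to new
#' samples.
#'
#' @param object a `mace_classifier`.
#' @param newdata a [count_matrix()] or counts matrix over (at least) the
#'   panel genes; gene ids must match the training ids.
#' @param ... unused.
#' @return data.frame with `sample_id`, `r_<group>` correlations, the two
#'   diagonal scores, `predicted` and `confident`.
#' @export
predict.mace_classifier <- function(object, newdata, ...) {
  m <- .counts_of(newdata)
  ref <- object$ref_log_geomeans
  common <- intersect(names(ref), rownames(m))
  if (length(common) < 2L)
    .stopf("newdata shares too few genes with the training reference")
  sf <- apply(log(m[common, , drop = FALSE]), 2L, function(lc) {
    r <- lc - ref[common]
    r <- r[is.finite(r)]
    if (!length(r)) .stopf("a new sample has no positive counts on reference genes")
    exp(stats::median(r))
  })
  absent <- setdiff(object$panel$gene_id, rownames(m))
  if (length(absent))
    .stopf("panel gene(s) absent from newdata: %s", paste(absent, collapse = ", "))
  norm <- sweep(m[object$panel$gene_id, , drop = FALSE], 2L, sf, `/`)
  prof <- if (object$correlation_scale == "log2norm")
    log2(norm + object$pseudocount) else norm
  r <- t(apply(prof, 2L, function(xc) {
    if (stats::sd(xc) == 0) return(rep(NA_real_, ncol(object$centroids)))
    apply(object$centroids, 2L, stats::cor, x = xc)
  }))
  colnames(r) <- paste0("r_", object$groups)
  out <- cbind(data.frame(sample_id = colnames(m), stringsAsFactors = FALSE),
               as.data.frame(r))
  attr(out, "groups") <- object$groups
  out <- diagonal_scores(out, object$groups)
  out$predicted <- ifelse(rowSums(is.na(r)) > 0L, NA_character_,
                          object$groups[apply(r, 1L, which.max)])
  axes <- attr(out, "axes")
  cut1 <- object$cutoffs$cutoffs[[axes[1L]]]
  cut2 <- object$cutoffs$cutoffs[[axes[2L]]]
  d1 <- out[[axes[1L]]]; d2 <- out[[axes[2L]]]
  out$confident <- ifelse(out$predicted == object$groups[1L], d1 >= cut1[["positive"]],
                   ifelse(out$predicted == object$groups[2L],
                          d1 <= -cut1[["negative"]] & d2 >= cut2[["positive"]],
                          d2 <= -cut2[["negative"]]))
  out
}

#' Score-plane plot of the leave-one-out classification
#'
#' Draws each sample in the plane of the two diagonal-distance scores
#' (x: group2 vs group3 axis, y: group1 vs group2 axis), colored by true
#' group, with the cutoff bands shaded.
#'
#' @param x a `mace_classifier`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mace_classifier <- function(x, ...) {
  axes <- attr(x$loo, "axes")
  d1 <- x$loo[[axes[1L]]]  # group1 vs group2 -> y axis
  d2 <- x$loo[[axes[2L]]]  # group2 vs group3 -> x axis
  cols <- stats::setNames(c("#D55E00", "#0072B2", "#009E73"), x$groups)
  xl <- range(d2) + c(-0.02, 0.02); yl <- range(d1) + c(-0.02, 0.02)
  graphics::plot(d2, d1, type = "n", xlim = xl, ylim = yl,
                 xlab = sprintf("score %s vs %s", x$groups[2L], x$groups[3L]),
                 ylab = sprintf("score %s vs %s", x$groups[1L], x$groups[2L]), ...)
  cut1 <- x$cutoffs$cutoffs[[axes[1L]]]; cut2 <- x$cutoffs$cutoffs[[axes[2L]]]
  shade <- function(x0, x1, y0, y1, col)
    graphics::rect(x0, y0, x1, y1, col = grDevices::adjustcolor(col, 0.15), border = NA)
  shade(xl[1L], xl[2L], cut1[["positive"]], yl[2L], cols[x$groups[1L]])
  shade(cut2[["positive"]], xl[2L], yl[1L], -cut1[["negative"]], cols[x$groups[2L]])
  shade(xl[1L], -cut2[["negative"]], yl[1L], -cut1[["negative"]], cols[x$groups[3L]])
  graphics::abline(h = 0, v = 0, col = "grey60", lty = 2)
  graphics::points(d2, d1, pch = 19, col = cols[x$loo$true_group])
  graphics::legend("topleft", legend = x$groups, col = cols, pch = 19, bty = "n")
  invisible(x)
}
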