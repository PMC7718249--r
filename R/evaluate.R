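#' Confusion matrix of true versus predicted labels
#'
#' @param truth,predicted equal-length label vectors; every label must be
#'   in `levels`.
#' @param levels group labels fixing row/column order (default: union of
#'   observed labels in appearance order).
#' @return integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    .stopf("truth and predicted must have the same length")
  levels <- levels %||% unique(c(truth, predicted))
  unknown <- setdiff(c(truth, predicted), levels)
  if (length(unknown))
    .stopf("unknown label(s): %s", paste(unique(unknown), collapse = ", "))
  tab <- table(factor(truth, levels), factor(predicted, levels))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- c("true", "predicted")
  m
}

#' One-vs-rest sensitivity and specificity for one class
#'
#' Sensitivity = TP / (all truly in the class); specificity =
#' TN / (all truly outside it). An empty true class yields `NA`
#' sensitivity.
#'
#' @param confusion matrix from [confusion_matrix()].
#' @param class class label (a row/column name).
#' @return named numeric vector `c(sensitivity, specificity)`, proportions
#'   in \[0, 1\].
#' @export
sensitivity_specificity <- function(confusion, class) {
  if (!class %in% rownames(confusion)) .stopf("class '%s' not in matrix", class)
  total <- sum(confusion)
  tp <- confusion[class, class]
  pos <- sum(confusion[class, ])
  fp <- sum(confusion[, class]) - tp
  neg <- total - pos
  c(sensitivity = if (pos == 0L) NA_real_ else tp / pos,
    specificity = if (neg == 0L) NA_real_ else (neg - fp) / neg)
}

#' Overall accuracy
#'
#' @param confusion matrix from [confusion_matrix()].
#' @return trace / total, in \[0, 1\].
#' @export
overall_accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0L) .stopf("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' One-vs-rest rank AUC per class
#'
#' For each class, samples are scored by the margin
#' `r_class - max(r_other)` and the area under the ROC curve is computed
#' rank-based (Mann-Whitney U / (n+ * n-)), ties counting 1/2. The macro
#' AUC is the unweighted mean over classes with at least one positive and
#' one negative.
#'
#' @param margins samples x classes numeric matrix of margin scores (or any
#'   per-class score where larger means more class-like).
#' @param truth true labels, length = rows of `margins`.
#' @return list with `per_class` (named vector, NA where undefined) and
#'   `macro`.
#' @export
one_vs_rest_auc <- function(margins, truth) {
  margins <- as.matrix(margins)
  truth <- as.character(truth)
  if (nrow(margins) != length(truth))
    .stopf("margins must have one row per sample")
  classes <- colnames(margins) %||% .stopf("margins must have class colnames")
  per <- vapply(classes, function(k) {
    pos <- truth == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      .warnf("class '%s' has no %s samples; AUC undefined",
             k, if (n1 == 0L) "positive" else "negative")
      return(NA_real_)
    }
    r <- rank(margins[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Margin scores from a correlation table
#'
#' `margin_k = r_k - max over other groups of r`, one column per group.
#'
#' @param cors data.frame with `r_<group>` columns (from
#'   [loo_correlations()]).
#' @param groups group labels (default: the `groups` attribute).
#' @return samples x groups matrix of margins.
#' @export
correlation_margins <- function(cors, groups = attr(cors, "groups")) {
  rmat <- as.matrix(cors[, paste0("r_", groups), drop = FALSE])
  colnames(rmat) <- groups
  out <- vapply(seq_along(groups), function(k) {
    rmat[, k] - apply(rmat[, -k, drop = FALSE], 1L, max)
  }, numeric(nrow(rmat)))
  dimnames(out) <- list(cors$sample_id, groups)
  out
}

#' Full classifier performance report
#'
#' Bundles the confusion matrix, per-class sensitivity/specificity,
#' overall accuracy and one-vs-rest AUCs computed from a classified
#' leave-one-out table.
#'
#' @param classified data.frame from [classify_samples()] (needs
#'   `true_group`, `predicted` and the `r_<group>` columns).
#' @param groups ordered group labels.
#' @return a `classifier_report` list: `confusion`, `sensitivity`,
#'   `specificity` (named proportions), `accuracy`, `auc` (per class +
#'   macro), `n`.
#' @export
classifier_report <- function(classified, groups = attr(classified, "groups")) {
  conf <- confusion_matrix(classified$true_group, classified$predicted, groups)
  ss <- vapply(groups, function(g) sensitivity_specificity(conf, g), numeric(2L))
  auc <- one_vs_rest_auc(correlation_margins(classified, groups),
                         classified$true_group)
  structure(list(confusion = conf,
                 sensitivity = ss["sensitivity", ],
                 specificity = ss["specificity", ],
                 accuracy = overall_accuracy(conf),
                 auc = auc, n = sum(conf), groups = groups),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Classifier performance (", x$n, " samples)\n\n", sep = "")
  print(x$confusion)
  cat("\n")
  for (g in x$groups)
    cat(sprintf("%-6s sensitivity %5.1f%%  specificity %5.1f%%  AUC %s\n", g,
                100 * x$sensitivity[[g]], 100 * x$specificity[[g]],
                ifelse(is.na(x$auc$per_class[[g]]), "NA",
                       sprintf("%.2f", x$auc$per_class[[g]]))))
  cat(sprintf("\nOverall accuracy %.1f%%  macro AUC %.2f\n",
              100 * x$accuracy, x$auc$macro))
  invisible(x)
}
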