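# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Step-up FDR straight from the definition: padj_(i) = min_{k>=i} m p_(k)/k.
bh_brute <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(vapply(i:m, function(k) m * pv[o[k]] / k, 0)))
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- adj
  out
}

# Product-moment correlation from the sum formula.
pearson_brute <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# O(n^2) pair-counting AUC with half-credit ties.
auc_brute <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# TP/FP/TN/FN counting for one class from raw label vectors.
sens_spec_brute <- function(truth, predicted, class) {
  tp <- sum(truth == class & predicted == class)
  fn <- sum(truth == class & predicted != class)
  tn <- sum(truth != class & predicted != class)
  fp <- sum(truth != class & predicted == class)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Double-loop version of the group-zero-mean gene filter.
filter_brute <- function(m, groups) {
  keep <- logical(nrow(m))
  for (g in seq_len(nrow(m))) {
    ok <- TRUE
    for (grp in unique(groups)) {
      if (mean(m[g, groups == grp]) == 0) ok <- FALSE
    }
    keep[g] <- ok
  }
  m[keep, , drop = FALSE]
}

# From-scratch leave-one-out centroid for one group and one held-out sample.
centroid_brute <- function(profiles, groups, group, exclude_id) {
  ids <- colnames(profiles)[groups == group]
  ids <- setdiff(ids, exclude_id)
  rowMeans(profiles[, ids, drop = FALSE])
}

tiny_sim <- function(...) simulate_counts(sim_config(n_genes = 300, seed = 11, ...))
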