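#' Marker-panel expression profiles
#'
#' Restricts the expression matrix to the panel genes, in panel order. The
#' default scale is `log2(normalized + pseudocount)`; the raw normalized
#' scale is available via `scale = "norm"`.
#'
#' @param normalized a `norm_matrix` from [normalize_counts()], or a plain
#'   genes x samples matrix already on the desired scale.
#' @param panel a `marker_panel` (or character vector of gene ids).
#' @param scale `"log2norm"` (default) or `"norm"`; ignored when
#'   `normalized` is a plain matrix.
#' @return panel-genes x samples numeric matrix.
#' @export
expression_profile <- function(normalized, panel, scale = c("log2norm", "norm")) {
  scale <- match.arg(scale)
  mat <- if (inherits(normalized, "norm_matrix")) {
    if (scale == "log2norm") normalized$log2 else normalized$norm
  } else as.matrix(normalized)
  genes <- if (is.data.frame(panel)) panel$gene_id else as.character(panel)
  absent <- setdiff(genes, rownames(mat))
  if (length(absent))
    .stopf("panel gene(s) absent from the matrix: %s",
           paste(absent, collapse = ", "))
  mat[genes, , drop = FALSE]
}

#' Per-group centroid expression
#'
#' Arithmetic mean per gene over each group's samples; an excluded sample
#' is removed from its own group's centroid only.
#'
#' @param profiles genes x samples matrix (typically from
#'   [expression_profile()]).
#' @param sheet sample sheet.
#' @param exclude optional single sample id to hold out.
#' @return genes x groups matrix of centroids.
#' @export
group_centroids <- function(profiles, sheet, exclude = NULL) {
  profiles <- as.matrix(profiles)
  sheet <- .align_sheet(profiles, sheet)
  idx <- .group_index(sheet)
  if (!is.null(exclude)) {
    if (!exclude %in% sheet$sample_id) .stopf("unknown sample '%s'", exclude)
    own <- as.character(sheet$group[sheet$sample_id == exclude])
    pos <- which(sheet$sample_id == exclude)
    idx[[own]] <- setdiff(idx[[own]], pos)
    if (!length(idx[[own]]))
      .stopf("excluding '%s' empties group '%s'", exclude, own)
  }
  vapply(idx, function(i) rowMeans(profiles[, i, drop = FALSE]),
         numeric(nrow(profiles)))
}

#' Leave-one-out correlations to group centroids
#'
#' For every sample, group centroids are recomputed with that sample held
#' out of its own group, and the Pearson correlation of the sample's panel
#' profile to each centroid is recorded. Samples with a zero-variance
#' profile cannot be correlated; they are dropped with a warning.
#'
#' @inheritParams group_centroids
#' @return data.frame with `sample_id`, `true_group` and one `r_<group>`
#'   column per group; attribute `groups` records the group order.
#' @export
loo_correlations <- function(profiles, sheet) {
  profiles <- as.matrix(profiles)
  sheet <- .align_sheet(profiles, sheet)
  idx <- .group_index(sheet)
  small <- names(idx)[lengths(idx) < 2L]
  if (length(small))
    .stopf("leave-one-out requires >= 2 samples per group; group '%s' has %d",
           small[1L], length(idx[[small[1L]]]))
  groups <- names(idx)
  rows <- lapply(seq_len(ncol(profiles)), function(j) {
    sid <- sheet$sample_id[j]
    x <- profiles[, j]
    if (stats::sd(x) == 0) {
      .warnf("sample '%s' has a zero-variance panel profile; not classifiable", sid)
      return(NULL)
    }
    cent <- group_centroids(profiles, sheet, exclude = sid)
    r <- apply(cent, 2L, function(cc) {
      if (stats::sd(cc) == 0) return(NA_real_)
      stats::cor(x, cc)
    })
    cbind(data.frame(sample_id = sid, true_group = as.character(sheet$group[j]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(r, paste0("r_", groups)))))
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}

#' Diagonal-distance scores from correlation triples
#'
#' Each sample's correlation pair is viewed as a point in the plane and
#' scored by its signed perpendicular distance from the slope-1 diagonal:
#' `d = (r_first - r_second) / sqrt(2)`, positive toward the first-named
#' group. With the canonical order (SCC, Pap, Ctrl) the two axes are SCC
#' vs Pap (positive suggests SCC) and Pap vs Ctrl (positive points toward
#' Pap).
#'
#' @param cors data.frame from [loo_correlations()].
#' @param groups ordered group labels (default: the `groups` attribute).
#' @return the input with score columns `d_<g1>_<g2>` and `d_<g2>_<g3>`
#'   appended.
#' @export
diagonal_scores <- function(cors, groups = attr(cors, "groups")) {
  if (length(groups) != 3L) .stopf("diagonal scores are defined for exactly 3 groups")
  r <- function(g) cors[[paste0("r_", g)]]
  axis1 <- paste0("d_", tolower(groups[1L]), "_", tolower(groups[2L]))
  axis2 <- paste0("d_", tolower(groups[2L]), "_", tolower(groups[3L]))
  cors[[axis1]] <- (r(groups[1L]) - r(groups[2L])) / sqrt(2)
  cors[[axis2]] <- (r(groups[2L]) - r(groups[3L])) / sqrt(2)
  attr(cors, "groups") <- groups
  attr(cors, "axes") <- c(axis1, axis2)
  cors
}

#' Cutoffs from the spread of a group's diagonal distances
#'
#' For each score axis and each side of the diagonal, the cutoff magnitude
#' is `c` times the sample standard deviation of the absolute scores of
#' the samples truly belonging to the group on that side (e.g. the positive
#' side of the SCC-vs-Pap axis uses the SCC samples). Scores beyond the
#' cutoff fall in the axis' area of significance.
#'
#' @param scores data.frame from [diagonal_scores()] (must include
#'   `true_group`).
#' @param c cutoff multiplier (default 1).
#' @return a `cutoff_set`: per axis, `c(positive, negative)` threshold
#'   magnitudes.
#' @export
determine_cutoffs <- function(scores, c = 1) {
  groups <- attr(scores, "groups")
  axes <- attr(scores, "axes")
  if (is.null(axes)) .stopf("scores must come from diagonal_scores()")
  side_groups <- list(c(groups[1L], groups[2L]), c(groups[2L], groups[3L]))
  out <- lapply(seq_along(axes), function(k) {
    d <- scores[[axes[k]]]
    vapply(c(positive = 1L, negative = 2L), function(side) {
      g <- side_groups[[k]][side]
      v <- abs(d[scores$true_group == g])
      if (length(v) < 2L)
        .stopf("cutoff for group '%s' needs >= 2 samples", g)
      c * stats::sd(v)
    }, numeric(1L))
  })
  names(out) <- axes
  structure(list(cutoffs = out, multiplier = c, groups = groups, axes = axes),
            class = "cutoff_set")
}

#' Classify samples from their centroid correlations
#'
#' The predicted class is the group with the highest correlation (the
#' pairwise "higher correlation" rule applied to all three groups); exact
#' ties resolve by the fixed group priority given by the group order
#' (canonically SCC > Pap > Ctrl). A prediction is `confident` iff the
#' sample's relevant diagonal scores lie beyond the cutoff band on the
#' predicted class' side: first group — score on axis 1 above the positive
#' cutoff; middle group — axis 1 below the negative cutoff and axis 2 above
#' the positive cutoff; last group — axis 2 below the negative cutoff.
#' Cutoffs gate confidence only; no sample abstains.
#'
#' @param scores data.frame from [diagonal_scores()].
#' @param cutoffs a `cutoff_set` from [determine_cutoffs()] (optional; when
#'   missing every prediction is marked confident).
#' @return the input with `predicted` and `confident` columns appended.
#' @export
classify_samples <- function(scores, cutoffs = NULL) {
  groups <- attr(scores, "groups")
  axes <- attr(scores, "axes")
  rmat <- as.matrix(scores[, paste0("r_", groups), drop = FALSE])
  pred <- groups[apply(rmat, 1L, which.max)]  # which.max: first max = priority order
  scores$predicted <- pred
  if (is.null(cutoffs)) {
    scores$confident <- TRUE
    return(scores)
  }
  d1 <- scores[[axes[1L]]]; d2 <- scores[[axes[2L]]]
  cut1 <- cutoffs$cutoffs[[axes[1L]]]; cut2 <- cutoffs$cutoffs[[axes[2L]]]
  scores$confident <- ifelse(pred == groups[1L], d1 >= cut1[["positive"]],
                      ifelse(pred == groups[2L],
                             d1 <= -cut1[["negative"]] & d2 >= cut2[["positive"]],
                             d2 <= -cut2[["negative"]]))
  scores
}
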