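#' Group-specific genes by overlap of pairwise upregulated sets
#'
#' A gene is specific for group G iff it is upregulated in G versus each of
#' the two other groups: `specific(G) = up(G vs H1) intersect up(G vs H2)`.
#' With DEG sets obeying the strict log2 fold-change sign constraint, the
#' three specific sets are pairwise disjoint.
#'
#' @param up_sets nested named list: `up_sets[[A]][[B]]` is the character
#'   vector of genes up in A versus B; both contrasts of every group must
#'   be present.
#' @param groups group labels (default: the names of `up_sets`).
#' @return named list mapping each group to its specific gene set
#'   (character vector, in the order of the first contrast's set).
#' @examples
#' up <- list(SCC = list(Ctrl = c("a", "b", "c"), Pap = c("b", "c", "d")))
#' group_specific_genes(up, groups = "SCC")
#' @export
group_specific_genes <- function(up_sets, groups = names(up_sets)) {
  out <- lapply(groups, function(g) {
    others <- setdiff(groups, g)
    if (length(others) == 0L) return(as.character(up_sets[[g]][[1L]]))
    sets <- lapply(others, function(h) {
      s <- up_sets[[g]][[h]]
      if (is.null(s))
        .stopf("missing upregulated set for contrast %s vs %s", g, h)
      as.character(s)
    })
    Reduce(intersect, sets)
  })
  names(out) <- groups
  out
}

#' Venn partition of two gene sets
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return named integer vector `c(shared, a_only, b_only)` with
#'   `|A| = shared + a_only` and `|B| = shared + b_only`.
#' @examples
#' venn_partition(letters[1:4], letters[3:6])  # 2, 2, 2
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  shared <- length(intersect(a, b))
  c(shared = shared, a_only = length(a) - shared, b_only = length(b) - shared)
}

#' Select the top expressed markers per group
#'
#' Within each group's specific set, genes are ranked by mean normalized
#' reads over that group's own samples (descending; ties broken
#' lexicographically by gene id) and the first `n_top` are taken. The panel
#' is the ordered union of the per-group blocks. A specific set smaller
#' than `n_top` contributes all its genes, with a warning.
#'
#' @param specific_sets named list from [group_specific_genes()].
#' @param normalized a `norm_matrix` from [normalize_counts()].
#' @param sheet sample sheet.
#' @param n_top genes per group (default 10, giving a 30-gene panel for
#'   three groups).
#' @return a `marker_panel` data.frame with columns `group`, `rank`,
#'   `gene_id`, `mean_norm`.
#' @export
select_top_markers <- function(specific_sets, normalized, sheet, n_top = 10L) {
  norm <- normalized$norm
  sheet <- .align_sheet(norm, sheet)
  idx <- .group_index(sheet, names(specific_sets))
  blocks <- lapply(names(specific_sets), function(g) {
    genes <- intersect(specific_sets[[g]], rownames(norm))
    dropped <- setdiff(specific_sets[[g]], rownames(norm))
    if (length(dropped))
      .stopf("specific genes for %s absent from the matrix: %s", g,
             paste(utils::head(dropped, 5L), collapse = ", "))
    if (length(genes) < n_top)
      .warnf("group %s has only %d specific gene(s) (< n_top = %d)",
             g, length(genes), n_top)
    mn <- rowMeans(norm[genes, idx[[g]], drop = FALSE])
    ord <- order(-mn, genes)
    take <- utils::head(ord, n_top)
    data.frame(group = rep(g, length(take)), rank = seq_along(take),
               gene_id = genes[take], mean_norm = unname(mn[take]),
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, blocks)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}
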