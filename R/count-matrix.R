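#' Gene-by-sample count container
#'
#' Bundles an integer gene x sample count matrix with per-gene feature
#' lengths (bp) and optional positional annotation, mirroring the columns of
#' a featureCounts output table. Gene ids are the rownames of `counts`,
#' sample ids the colnames; both must be unique.
#'
#' @param counts numeric matrix of non-negative integer counts with gene ids
#'   as rownames and sample ids as colnames.
#' @param lengths positive feature lengths in bp, one per gene (recycled name
#'   check against gene ids when named). Required for TPM computation only;
#'   defaults to 1000 bp for every gene when omitted.
#' @param annotation optional data.frame of opaque positional columns
#'   (Chr/Start/End/Strand) carried through to [write_fixture()].
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `lengths` and `annotation`.
#' @examples
#' m <- matrix(0:5, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' cm <- count_matrix(m, lengths = c(500L, 1500L))
#' dim(cm)
#' @export
count_matrix <- function(counts, lengths = NULL, annotation = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    .stopf("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate gene ids: %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicate sample ids: %s",
           paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) && nrow(counts) > 0L)
    .stopf("counts must be numeric")
  if (nrow(counts) > 0L) {
    if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
      .stopf("counts must be finite non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    .stopf("need one feature length per gene (%d given, %d genes)",
           length(lengths), nrow(counts))
  if (nrow(counts) > 0L && any(!is.finite(lengths) | lengths <= 0))
    .stopf("feature lengths must be positive")
  names(lengths) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths, annotation = annotation),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts)) cat("samples:", paste(utils::head(colnames(x$counts), 8L), collapse = ", "),
                          if (ncol(x$counts) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  counts <- x$counts[i, j, drop = FALSE]
  ann <- x$annotation
  if (!is.null(ann) && !missing(i)) ann <- ann[i, , drop = FALSE]
  count_matrix(counts, x$lengths[rownames(counts)], ann)
}
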